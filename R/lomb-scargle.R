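#' Lomb-Scargle periodogram of a singing series
#'
#' Computes the classic normalized Lomb-Scargle power spectrum of a
#' per-minute series over a grid of candidate periods (default 18-30 h in
#' 0.02-h steps, comfortably finer than 0.05 h at 24 h). Masked minutes are
#' simply excluded — LS handles the resulting irregular sampling natively,
#' which is the reason it is the standard periodogram for gappy behavioural
#' records. Power is normalized by the sample variance, so under the
#' white-noise null each power is approximately unit-exponential and the
#' alpha-level significance threshold has the closed form of
#' [ls_significance_threshold()].
#'
#' @param series A `singing_series`, or any data frame with numeric columns
#'   `t_h` (hours) and `value` (and optionally logical `masked`).
#' @param period_range Candidate period bounds in hours.
#' @param period_step Grid step in hours.
#' @param alpha Significance level for the rhythmicity test.
#' @param m_independent Number of independent frequencies used by the
#'   threshold; defaults to the count of natural Fourier frequencies of the
#'   observation span falling inside `period_range` (a Horne-Baliunas-style
#'   estimate).
#' @return An `ls_periodogram`: list with `spectrum` (tibble `period_h`,
#'   `power`), `threshold`, `alpha`, `best_period` (the grid maximum refined
#'   by parabolic interpolation through its neighbours, so estimates are not
#'   quantised to the grid; `NA` when nothing exceeds the threshold),
#'   `is_rhythmic`, `peak_power`, `n`.
#' @examples
#' s <- simulate_series(song_schedule(period_h = 25, p_sing = 1,
#'                                    p_noise_sing = 0),
#'                      photoschedule("DD"), days = 8, seed = 1)
#' glance(lomb_scargle(s))
#' @export
lomb_scargle <- function(series, period_range = c(18, 30),
                         period_step = 0.02, alpha = 0.05,
                         m_independent = NULL) {
  df <- as_tibble(series)
  if ("masked" %in% names(df)) df <- df[!df$masked, , drop = FALSE]
  t <- df$t_h
  x <- df$value
  span <- diff(range(t))
  if (span < 3 * max(period_range)) {
    stop_invalid("need at least 3 cycles of the longest candidate period (",
                 3 * max(period_range), " h of unmasked data; have ",
                 round(span, 1), " h).")
  }
  periods <- seq(period_range[1], period_range[2], by = period_step)
  n <- length(x)
  xc <- x - mean(x)
  ss <- sum(xc^2)
  if (is.null(m_independent)) {
    m_independent <- max(1L, floor(span * (1 / min(period_range) -
                                             1 / max(period_range))))
  }
  threshold <- ls_significance_threshold(alpha, m_independent)
  if (ss == 0) { # constant series: zero power everywhere, not rhythmic
    spec <- tibble(period_h = periods, power = 0)
    return(new_ls_periodogram(spec, threshold, alpha, n))
  }
  sigma2 <- ss / (n - 1)
  power <- vapply(periods, function(p) {
    w <- 2 * pi / p
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    arg <- w * (t - tau)
    cs <- cos(arg); sn <- sin(arg)
    (sum(xc * cs)^2 / sum(cs^2) + sum(xc * sn)^2 / sum(sn^2)) / (2 * sigma2)
  }, numeric(1))
  new_ls_periodogram(tibble(period_h = periods, power = power),
                     threshold, alpha, n)
}

new_ls_periodogram <- function(spectrum, threshold, alpha, n) {
  peak_power <- max(spectrum$power)
  is_rhythmic <- peak_power > threshold
  structure(
    list(spectrum = spectrum, threshold = threshold, alpha = alpha,
         best_period = if (is_rhythmic) {
           refine_peak(spectrum$period_h, spectrum$power)
         } else NA_real_,
         peak_power = peak_power, is_rhythmic = is_rhythmic, n = n),
    class = "ls_periodogram"
  )
}

#' @export
print.ls_periodogram <- function(x, ...) {
  cat(sprintf(
    "<ls_periodogram> best period %s h | peak power %.2f vs threshold %.2f (alpha %.3g) | %s\n",
    ifelse(x$is_rhythmic, sprintf("%.2f", x$best_period), "none"),
    x$peak_power, x$threshold, x$alpha,
    if (x$is_rhythmic) "rhythmic" else "not rhythmic"))
  invisible(x)
}

# Sub-grid refinement of the periodogram maximum: a parabola through the
# peak bin and its neighbours. Removes the quantisation of best-period
# estimates to the period grid; falls back to the grid value at the edges.
refine_peak <- function(period, power) {
  k <- which.max(power)
  if (k == 1 || k == length(power)) return(period[k])
  y1 <- power[k - 1]; y2 <- power[k]; y3 <- power[k + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom >= 0) return(period[k]) # not a proper local maximum
  period[k] + 0.5 * (y1 - y3) / denom * (period[k] - period[k - 1])
}

#' Significance threshold for Lomb-Scargle power
#'
#' Under the white-noise null, each normalized LS power is approximately
#' exponential, so with `m` independent frequencies the alpha-level
#' threshold is `z* = -ln(1 - (1 - alpha)^(1/m))`; a peak above `z*`
#' rejects non-rhythmicity at level alpha.
#'
#' @param alpha Significance level in (0, 1).
#' @param m Number of independent frequencies (>= 1).
#' @return The power threshold `z*`.
#' @examples
#' ls_significance_threshold(0.05, 1) # -ln(0.05) = 2.996
#' @export
ls_significance_threshold <- function(alpha = 0.05, m = 1) {
  if (alpha <= 0 || alpha >= 1) stop_invalid("`alpha` must be in (0, 1).")
  if (m < 1) stop_invalid("`m` must be >= 1.")
  -log(1 - (1 - alpha)^(1 / m))
}

#' Summarise best periods by treatment group
#'
#' Per-group mean, standard error and n of individual best-period
#' estimates, plus a pooled row across all individuals. Single-member
#' groups report a missing SE.
#'
#' @param periods Data frame with a period column and a group column.
#' @param period_col,group_col Column names.
#' @return Tibble with `group`, `n`, `mean_period_h`, `se_period_h`
#'   (pooled row has group `"pooled"`).
#' @export
period_summary <- function(periods, period_col = "best_period",
                           group_col = "group") {
  p <- periods[[period_col]]
  g <- periods[[group_col]]
  per <- tibble(group = as.character(g), period = p) %>%
    filter(!is.na(.data$period)) %>%
    group_by(group = .data$group) %>%
    summarise(n = dplyr::n(), mean_period_h = mean(.data$period),
              se_period_h = if_else(dplyr::n() > 1,
                                    sd(.data$period) / sqrt(dplyr::n()),
                                    NA_real_),
              .groups = "drop")
  ok <- !is.na(p)
  pooled <- tibble(group = "pooled", n = sum(ok),
                   mean_period_h = mean(p[ok]),
                   se_period_h = if (sum(ok) > 1) {
                     sd(p[ok]) / sqrt(sum(ok))
                   } else NA_real_)
  bind_rows(per, pooled)
}

#' Permutation test for equality of periods across groups
#'
#' Tests whether best-period distributions differ between treatment groups
#' (e.g. temperatures, to probe temperature compensation) by permuting group
#' labels. The statistic is the group-size-weighted between-group sum of
#' squares of mean periods; the p-value is the permutation tail probability
#' (with the add-one correction).
#'
#' @param periods Numeric vector of best periods.
#' @param groups Group labels, same length.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Tibble with `statistic`, `p_value`, `n_perm`.
#' @export
period_permutation_test <- function(periods, groups, n_perm = 1000,
                                    seed = 1L) {
  ok <- !is.na(periods)
  periods <- periods[ok]; groups <- as.character(groups)[ok]
  if (length(unique(groups)) < 2) {
    stop_invalid("need at least two groups.")
  }
  stat <- function(p, g) {
    gm <- tapply(p, g, mean); gn <- tapply(p, g, length)
    sum(gn * (gm - mean(p))^2)
  }
  obs <- stat(periods, groups)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) stat(periods, sample(groups)), numeric(1))
  })
  tibble(statistic = obs,
         p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
         n_perm = n_perm)
}
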