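#' Circular statistics on a 24-hour clock
#'
#' Phase markers live on a 24-h circle, so ordinary means mislead near
#' midnight; these helpers map hours to angles (`h * 2 * pi / 24`), average
#' the unit vectors, and map back. `circular_mean()` is
#' rotation-equivariant; `mean_resultant_length()` (R-bar) and the angular
#' variance `V_m = 1 - R-bar` are rotation-invariant, with `V_m = 0` for
#' perfectly concentrated phases and `V_m = 1` for balanced (e.g. uniform)
#' phases.
#'
#' @param hours Numeric vector of times in hours (`NA`s dropped).
#' @param period Circle period in hours (default 24).
#' @return `circular_mean()`: mean hour in `[0, period)`;
#'   `mean_resultant_length()`: R-bar in `[0, 1]`;
#'   `angular_variance()`: `V_m` in `[0, 1]`.
#' @examples
#' circular_mean(c(23, 1))        # 0
#' angular_variance(c(0, 6, 12, 18)) # 1
#' @export
circular_mean <- function(hours, period = 24) {
  hours <- hours[!is.na(hours)]
  if (length(hours) == 0) return(NA_real_)
  a <- hours * 2 * pi / period
  h <- (atan2(mean(sin(a)), mean(cos(a))) * period / (2 * pi)) %% period
  if (period - h < 1e-9) 0 else h # snap the wrap point to 0
}

#' @rdname circular_mean
#' @export
mean_resultant_length <- function(hours, period = 24) {
  hours <- hours[!is.na(hours)]
  if (length(hours) == 0) return(NA_real_)
  a <- hours * 2 * pi / period
  sqrt(mean(sin(a))^2 + mean(cos(a))^2)
}

#' @rdname circular_mean
#' @export
angular_variance <- function(hours, period = 24) {
  1 - mean_resultant_length(hours, period)
}

#' Circular summary of a set of phases
#'
#' @inheritParams circular_mean
#' @return One-row tibble: `mean_zt`, `r_bar`, `v_m`, `n`.
#' @export
circular_summary <- function(hours, period = 24) {
  hours <- hours[!is.na(hours)]
  tibble(mean_zt = circular_mean(hours, period),
         r_bar = mean_resultant_length(hours, period),
         v_m = angular_variance(hours, period),
         n = length(hours))
}

# Signed shortest-arc difference a - b on the circle, in (-period/2, period/2].
circular_diff <- function(a, b, period = 24) {
  d <- (a - b) %% period
  if_else(d > period / 2, d - period, d)
}

#' Phase shift between two regimes
#'
#' Quantifies how a phase marker moved between two photoschedule regimes
#' (each referenced to its own lights-on): the shortest-arc difference
#' between the circular means, signed so that an **advance** (the marker
#' occurring earlier in the new regime) is **positive** and a delay
#' negative. Significance is assessed by a permutation test that shuffles
#' regime labels over the per-day marker values.
#'
#' @param pre_hours,post_hours Per-day marker values (ZT h) under the
#'   reference and the shifted regime.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param period Circle period (h).
#' @return One-row tibble: `shift_h` (advance > 0), `p_value`, `n_pre`,
#'   `n_post`.
#' @examples
#' phase_shift(c(13.2, 13.3), c(12.3, 12.4))$shift_h # ~ +0.9 advance
#' @export
phase_shift <- function(pre_hours, post_hours, n_perm = 10000, seed = 1L,
                        period = 24) {
  pre_hours <- pre_hours[!is.na(pre_hours)]
  post_hours <- post_hours[!is.na(post_hours)]
  if (length(pre_hours) == 0 || length(post_hours) == 0) {
    stop_invalid("need at least one defined marker per regime.")
  }
  obs <- circular_diff(circular_mean(pre_hours, period),
                       circular_mean(post_hours, period), period)
  pooled <- c(pre_hours, post_hours)
  n1 <- length(pre_hours)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), n1)
      abs(circular_diff(circular_mean(pooled[idx], period),
                        circular_mean(pooled[-idx], period), period))
    }, numeric(1))
  })
  tibble(shift_h = obs,
         p_value = (1 + sum(perm >= abs(obs))) / (n_perm + 1),
         n_pre = n1, n_post = length(post_hours))
}
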