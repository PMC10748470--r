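#' Build a per-minute singing series from clip predictions
#'
#' Clips are 60 s, so predictions map 1:1 onto minutes. Minutes absent from
#' `predictions` (e.g. equipment failure) are masked, not dropped, so the
#' series stays anchored to clock time and Zeitgeber time.
#'
#' @param predictions Tibble with integer column `minute` (0-based elapsed
#'   minute) and binary column `prediction`.
#' @param sched The [photoschedule()] in force.
#' @param id Individual identifier.
#' @param n_minutes Series length; defaults to `max(minute) + 1`.
#' @param start Start datetime (first lights-on).
#' @return A `singing_series` tibble (see [simulate_series()] for columns).
#' @export
binarize_scores <- function(predictions, sched, id = "ind",
                            n_minutes = NULL,
                            start = as.POSIXct("2023-01-01 00:00:00",
                                               tz = "UTC")) {
  if (nrow(predictions) == 0) {
    warn("empty prediction set; returning empty series.")
    n_minutes <- 0L
  }
  if (is.null(n_minutes)) n_minutes <- max(predictions$minute) + 1L
  minute <- seq_len(n_minutes) - 1L
  t_h <- minute / 60
  value <- rep(NA_integer_, n_minutes)
  value[predictions$minute + 1L] <- as.integer(predictions$prediction)
  gap <- is.na(value)
  start <- start + sched$lights_on * 3600
  tbl <- tibble(
    id = id, minute = minute, datetime = start + minute * 60, t_h = t_h,
    zt = zt_at(sched, t_h), phase = phase_at(sched, t_h),
    regime = regime_at(sched, t_h),
    value = if_else(gap, 0L, value),
    masked = gap
  )
  new_singing_series(tbl, sched, start)
}

#' Mask a gap in a series
#'
#' Marks a span of minutes as missing (equipment failure, etc.); masked
#' minutes are excluded from every aggregate but keep their time stamps.
#'
#' @param series A `singing_series`.
#' @param from_minute,to_minute Inclusive 0-based minute range to mask.
#' @return The series with the gap masked.
#' @export
mask_gap <- function(series, from_minute, to_minute) {
  series$masked <- series$masked |
    (series$minute >= from_minute & series$minute <= to_minute)
  series
}

#' Apply the standard trimming rules
#'
#' Masks (never deletes) the first `drop_start_h` hours of a series
#' (acclimation to experimental conditions; default 72 h) and, when the
#' photoschedule has an LD -> DL reversal, the first `drop_post_reversal_d`
#' days after the reversal (transient cycles; default 4).
#'
#' @param series A `singing_series`.
#' @param drop_start_h Hours masked from the start.
#' @param drop_post_reversal_d Days masked from the reversal on.
#' @return The trimmed series. Errors if nothing unmasked remains.
#' @export
trim_days <- function(series, drop_start_h = 72, drop_post_reversal_d = 4) {
  sched <- attr(series, "photoschedule")
  series$masked <- series$masked | series$t_h < drop_start_h
  if (!is.null(sched$reversal_day)) {
    r0 <- sched$reversal_day * 24
    series$masked <- series$masked |
      (series$t_h >= r0 & series$t_h < r0 + drop_post_reversal_d * 24)
  }
  if (all(series$masked)) {
    stop_invalid("series fully masked after trimming (shorter than ",
                 drop_start_h, " h of usable data).")
  }
  series
}

unmasked <- function(series) series[!series$masked, , drop = FALSE]

#' Daily singing effort
#'
#' The average number of hours per day during which the cricket sang at
#' least once per minute: total unmasked singing minutes divided by the
#' number of days contributing unmasked data, in hours.
#'
#' @param series A binary `singing_series`.
#' @return Singing effort in hours per day.
#' @export
singing_effort <- function(series) {
  u <- unmasked(series)
  if (nrow(u) == 0) stop_invalid("no unmasked minutes in series.")
  days <- length(unique(u$minute %/% 1440L))
  sum(u$value) / days / 60
}

#' Fraction of the dark and light phases spent singing
#'
#' For a binary individual series: the fraction of unmasked dark-phase
#' (resp. light-phase) minutes containing song. Under DD, subjective phases
#' carried from the prior schedule are used.
#'
#' @param series A binary `singing_series`.
#' @return A tibble with columns `dark_fraction` and `light_fraction`.
#' @export
phase_activity_fraction <- function(series) {
  u <- unmasked(series)
  dark <- u$phase %in% c("dark", "subjective_dark")
  frac <- function(sel) {
    if (!any(sel)) return(NA_real_)
    mean(u$value[sel] >= 1)
  }
  tibble(dark_fraction = frac(dark), light_fraction = frac(!dark))
}

#' Average a group of aligned series
#'
#' Per-minute mean over the individuals with unmasked data at that minute
#' (the group value is fractional in `[0, 1]`); minutes where no member has
#' data stay masked.
#'
#' @param series_list List of `singing_series` on an identical time base.
#' @param id Identifier for the group series.
#' @return A fractional `singing_series`.
#' @export
average_group <- function(series_list, id = "group") {
  stopifnot(length(series_list) >= 1)
  n <- nrow(series_list[[1]])
  for (s in series_list) {
    if (nrow(s) != n || !all(s$minute == series_list[[1]]$minute)) {
      stop_invalid("series do not share a time base.")
    }
  }
  vals <- sapply(series_list, function(s) ifelse(s$masked, NA_real_, s$value))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = n)
  m <- rowMeans(vals, na.rm = TRUE)
  out <- series_list[[1]]
  out$id <- id
  out$value <- ifelse(is.nan(m), 0, m)
  out$masked <- apply(is.na(vals), 1, all)
  out
}

#' Double-plotted actogram matrix
#'
#' The conventional chronobiology raster: one row per day, 48 h per row, the
#' second 24 h of row *d* re-plotted as the first 24 h of row *d + 1*.
#' Masked minutes are `NA`.
#'
#' @param series A `singing_series`.
#' @return An `actogram`: a `days - 1` (or 1) by 2880 matrix with attributes
#'   `photoschedule` and `bin_min`.
#' @export
build_actogram <- function(series) {
  v <- ifelse(series$masked, NA_real_, series$value)
  days <- ceiling(length(v) / 1440)
  length(v) <- days * 1440
  day_mat <- matrix(v, nrow = days, byrow = TRUE)
  n_rows <- max(days - 1, 1)
  out <- matrix(NA_real_, n_rows, 2880)
  for (d in seq_len(n_rows)) {
    out[d, 1:1440] <- day_mat[d, ]
    if (d + 1 <= days) out[d, 1441:2880] <- day_mat[d + 1, ]
  }
  structure(out, class = "actogram",
            photoschedule = attr(series, "photoschedule"), bin_min = 1)
}

#' Wrapped polar activity profile
#'
#' Mean singing value per ZT bin (default 30 min, 48 bins), wrapped across
#' all unmasked days: the profile behind polar plots of nightly activity.
#'
#' @param series A `singing_series`.
#' @param bin_min Bin width in minutes (must divide 1440).
#' @return Tibble with `zt` (bin start, h), `value` (mean in `[0, 1]`) and
#'   `n` (unmasked minutes contributing).
#' @export
polar_profile <- function(series, bin_min = 30) {
  if (1440 %% bin_min != 0) stop_invalid("`bin_min` must divide 1440.")
  u <- unmasked(series)
  bins <- tibble(zt = (seq_len(1440 %/% bin_min) - 1) * bin_min / 60)
  if (nrow(u) == 0) {
    return(mutate(bins, value = NA_real_, n = 0L))
  }
  prof <- u %>%
    mutate(zt_bin = floor(.data$zt * 60 / bin_min + 1e-6) * bin_min / 60) %>%
    group_by(zt_bin = .data$zt_bin) %>%
    summarise(value = mean(.data$value), n = dplyr::n(), .groups = "drop")
  bins %>%
    left_join(prof, by = c(zt = "zt_bin")) %>%
    mutate(n = if_else(is.na(.data$n), 0L, .data$n))
}
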