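#' Daily phase markers by the 20%-of-peak rule
#'
#' For each day of a series, bins the (unmasked) per-minute activity into
#' ZT bins (default 30 min), optionally smooths the daily profile with a
#' centred circular moving average, and extracts three phase markers:
#'
#' * **peak**: the ZT of the profile maximum within the 24-h day (circular
#'   midpoint when adjacent bins tie);
#' * **onset**: the last upward crossing of 20% of the peak value before
#'   the peak (searching back at most 24 h, circularly), linearly
#'   interpolated between bins — the "last" rule keeps sporadic pre-onset
#'   chirps from pulling onset early;
#' * **offset**: the first downward 20% crossing after the peak, likewise
#'   interpolated.
#'
#' Bin values are means over the bin timestamped at the bin's left edge, so
#' minute-resolution data (`bin_min = 1`) treat the series as samples at
#' minute starts and the interpolated crossings of a piecewise-linear
#' profile are exact. Days with no unmasked data, no activity, or a peak
#' below `min_peak` return missing markers — they are recorded as
#' undefined, never fabricated.
#'
#' @param series A `singing_series`.
#' @param bin_min Bin width in minutes (must divide 1440).
#' @param smooth_bins Width (odd, in bins) of the centred circular moving
#'   average; 1 disables smoothing.
#' @param min_peak Minimum smoothed peak value for markers to be defined.
#' @return A `phase_markers` tibble: `id`, `day` (0-based), `onset_zt`,
#'   `peak_zt`, `offset_zt` (ZT hours in `[0, 24)`, `NA` when undefined).
#' @examples
#' s <- simulate_series(song_schedule(p_sing = 1, p_noise_sing = 0),
#'                      photoschedule("DL", 18), days = 2, seed = 1)
#' phase_markers(s, smooth_bins = 1)
#' @export
phase_markers <- function(series, bin_min = 30, smooth_bins = 3,
                          min_peak = 0.1) {
  if (1440 %% bin_min != 0) stop_invalid("`bin_min` must divide 1440.")
  if (smooth_bins < 1 || smooth_bins %% 2 != 1) {
    stop_invalid("`smooth_bins` must be odd and >= 1.")
  }
  df <- as_tibble(series)
  days <- sort(unique(df$minute %/% 1440L))
  id <- if (!is.null(df$id)) df$id[1] else "series"
  out <- lapply(days, function(d) {
    day_df <- df[df$minute %/% 1440L == d & !df$masked, , drop = FALSE]
    mk <- day_markers(day_df, bin_min, smooth_bins, min_peak)
    tibble(id = id, day = d, onset_zt = mk[1], peak_zt = mk[2],
           offset_zt = mk[3])
  })
  structure(bind_rows(out),
            class = c("phase_markers", class(tibble())),
            config = list(bin_min = bin_min, smooth_bins = smooth_bins,
                          min_peak = min_peak))
}

# One day's (onset, peak, offset), or NAs when undefined.
day_markers <- function(day_df, bin_min, smooth_bins, min_peak) {
  undefined <- c(NA_real_, NA_real_, NA_real_)
  if (nrow(day_df) == 0) return(undefined)
  nb <- 1440L %/% bin_min
  bin_h <- bin_min / 60
  # epsilon guards against minute/60*60 landing a hair below the bin edge
  idx <- floor(day_df$zt * 60 / bin_min + 1e-6) + 1L
  v <- rep(NA_real_, nb)
  agg <- tapply(day_df$value, idx, mean)
  v[as.integer(names(agg))] <- agg
  if (all(is.na(v))) return(undefined)
  v[is.na(v)] <- 0 # bins fully masked contribute no activity
  if (smooth_bins > 1) {
    half <- (smooth_bins - 1) / 2
    vpad <- c(tail(v, half), v, head(v, half))
    v <- vapply(seq_len(nb),
                function(i) mean(vpad[i:(i + smooth_bins - 1)]), numeric(1))
  }
  peak_val <- max(v)
  if (peak_val <= 0 || peak_val < min_peak) return(undefined)
  t_bins <- (seq_len(nb) - 1L) * bin_h
  peak_set <- which(v == peak_val)
  pk <- peak_set[1]
  peak_zt <- if (length(peak_set) > 1 &&
                 all(diff(peak_set) == 1)) {
    mean(t_bins[peak_set]) # contiguous tie: midpoint
  } else {
    t_bins[pk]
  }
  thr <- 0.2 * peak_val
  onset <- NA_real_
  for (back in seq_len(nb)) { # walk back from the peak, <= 24 h
    i <- ((pk - 1 - back) %% nb) + 1L
    ip1 <- (i %% nb) + 1L
    if (v[i] < thr && v[ip1] >= thr) {
      onset <- (t_bins[i] + (thr - v[i]) / (v[ip1] - v[i]) * bin_h) %% 24
      break
    }
  }
  offset <- NA_real_
  for (fwd in seq_len(nb)) { # walk forward from the peak
    i <- ((pk - 1 + fwd) %% nb) + 1L
    im1 <- ((i - 2) %% nb) + 1L
    if (v[i] < thr && v[im1] >= thr) {
      offset <- (t_bins[im1] + (v[im1] - thr) / (v[im1] - v[i]) * bin_h) %% 24
      break
    }
  }
  c(onset, peak_zt, offset)
}
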