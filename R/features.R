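#' Welch-averaged magnitude spectrum of a clip, restricted to a band
#'
#' Splits the clip into Hann-windowed frames (default 4096 samples, 50%
#' overlap), averages the per-frame periodograms, and returns the magnitude
#' spectrum restricted to `[fmin, fmax]` — the 3-6 kHz band containing the
#' cricket calling song by default. Frequency resolution
#' (`sample_rate / frame`) is recorded as an attribute.
#'
#' @param samples Numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate Samples per second.
#' @param fmin,fmax Band bounds in Hz; `fmax` must not exceed Nyquist.
#' @param frame Frame length in samples.
#' @param overlap Fractional frame overlap in `[0, 1)`.
#' @return A tibble with columns `freq_hz` and `mag` (root of the averaged
#'   periodogram power), attributes `resolution_hz` and `band`.
#' @export
band_spectrum <- function(samples, sample_rate = 44100, fmin = 3000,
                          fmax = 6000, frame = 4096, overlap = 0.5) {
  sp <- welch_spectrum(samples, sample_rate, frame, overlap)
  keep <- sp$freq_hz >= fmin & sp$freq_hz <= fmax
  out <- sp[keep, ]
  attr(out, "resolution_hz") <- sample_rate / frame
  attr(out, "band") <- c(fmin, fmax)
  out
}

# Full-range Welch periodogram (power), tibble(freq_hz, power, mag).
welch_spectrum <- function(samples, sample_rate, frame = 4096,
                           overlap = 0.5) {
  n <- length(samples)
  if (n < frame) {
    stop_invalid("clip shorter than one analysis frame (", frame, " samples).")
  }
  if (frame > 0 && sample_rate / 2 < 0) stop_invalid("bad sample rate")
  hop <- max(1L, as.integer(round(frame * (1 - overlap))))
  starts <- seq(1L, n - frame + 1L, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(frame) - 1) / frame)) # Hann
  wnorm <- sum(win^2)
  nb <- frame %/% 2 + 1L
  acc <- numeric(nb)
  for (s in starts) {
    fr <- samples[s:(s + frame - 1L)] * win
    p <- Mod(fft(fr))^2 / wnorm
    acc <- acc + p[seq_len(nb)]
  }
  power <- acc / length(starts)
  tibble(freq_hz = (seq_len(nb) - 1L) * sample_rate / frame,
         power = power, mag = sqrt(power))
}

# Envelope as 10-ms block RMS (cheap, scale-linear).
block_envelope <- function(samples, sample_rate, block_s = 0.01) {
  b <- max(1L, as.integer(round(block_s * sample_rate)))
  nb <- length(samples) %/% b
  if (nb < 1) return(sqrt(mean(samples^2)))
  m <- matrix(samples[seq_len(nb * b)]^2, nrow = b)
  sqrt(colMeans(m))
}

moment_skewness <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

moment_kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

#' Feature catalogues
#'
#' `feature_catalogue("default")` names the five descriptors used by the
#' stock classifier; `feature_catalogue("full")` names the complete
#' 19-descriptor set from which the default was pared.
#'
#' @param which `"default"` (5 features) or `"full"` (19).
#' @return Character vector of feature names in their fixed order.
#' @export
feature_catalogue <- function(which = c("default", "full")) {
  which <- match.arg(which)
  default <- c("dominant_freq_hz", "band_energy_ratio", "band_entropy",
               "band_mag_sd", "crest_factor")
  if (which == "default") return(default)
  c(default,
    "band_mag_mean", "band_mag_median", "band_mag_skewness",
    "band_mag_kurtosis", "band_flatness", "band_centroid_hz",
    "band_bandwidth_hz", "band_rolloff_hz", "env_mean", "env_sd",
    "zero_crossing_rate", "env_peak_count", "broadband_rms",
    "band_power_total")
}

#' Compute spectral features of one clip
#'
#' Computes band-limited (3-6 kHz by default) spectral descriptors of a
#' clip, the classifier's inputs. The default catalogue is five features:
#' band dominant frequency, band-to-total energy ratio, normalized band
#' spectral entropy, band magnitude SD, and temporal-envelope crest factor.
#' The full catalogue adds 14 further descriptors (band magnitude moments,
#' flatness, centroid/bandwidth/rolloff, envelope statistics, zero-crossing
#' rate, envelope peak count, broadband RMS, total band power).
#'
#' A silent clip never errors: by convention its entropy and flatness are 1
#' (the uniform limit) and its dominant frequency, centroid, bandwidth and
#' rolloff are `NaN` (flagged as undefined).
#'
#' @inheritParams band_spectrum
#' @param catalogue Character vector of feature names (a subset of
#'   `feature_catalogue("full")`), or the result of [feature_catalogue()].
#' @return A one-row tibble with one column per requested feature, in
#'   catalogue order.
#' @export
compute_features <- function(samples, sample_rate = 44100,
                             catalogue = feature_catalogue("default"),
                             fmin = 3000, fmax = 6000, frame = 4096,
                             overlap = 0.5) {
  unknown <- setdiff(catalogue, feature_catalogue("full"))
  if (length(catalogue) == 0 || length(unknown) > 0) {
    stop_invalid("unknown feature(s): ", paste(unknown, collapse = ", "))
  }
  if (fmax > sample_rate / 2) stop_invalid("`fmax` exceeds Nyquist.")
  sp <- welch_spectrum(samples, sample_rate, frame, overlap)
  inb <- sp$freq_hz >= fmin & sp$freq_hz <= fmax
  bp <- sp$power[inb]
  bm <- sp$mag[inb]
  bf <- sp$freq_hz[inb]
  tot <- sum(sp$power)
  btot <- sum(bp)
  silent_band <- btot == 0

  pnorm_band <- if (silent_band) rep(1 / length(bp), length(bp)) else bp / btot
  entropy <- -sum(ifelse(pnorm_band > 0, pnorm_band * log(pnorm_band), 0)) /
    log(length(bp))
  centroid <- if (silent_band) NaN else sum(bf * pnorm_band)
  env <- block_envelope(samples, sample_rate)
  env_rms <- sqrt(mean(env^2))

  vals <- list(
    dominant_freq_hz = if (silent_band) NaN else bf[which.max(bm)],
    band_energy_ratio = if (tot == 0) 0 else btot / tot,
    band_entropy = entropy,
    band_mag_sd = sd(bm),
    crest_factor = if (env_rms == 0) 1 else max(env) / env_rms,
    band_mag_mean = mean(bm),
    band_mag_median = median(bm),
    band_mag_skewness = moment_skewness(bm),
    band_mag_kurtosis = moment_kurtosis(bm),
    band_flatness = if (silent_band) 1 else
      exp(mean(log(pmax(bp, .Machine$double.xmin)))) / mean(bp),
    band_centroid_hz = centroid,
    band_bandwidth_hz = if (silent_band) NaN else
      sqrt(sum((bf - centroid)^2 * pnorm_band)),
    band_rolloff_hz = if (silent_band) NaN else
      bf[which(cumsum(bp) >= 0.85 * btot)[1]],
    env_mean = mean(env),
    env_sd = sd(env),
    zero_crossing_rate = mean(diff(sign(samples + (samples == 0))) != 0),
    env_peak_count = count_envelope_peaks(env),
    broadband_rms = sqrt(mean(samples^2)),
    band_power_total = btot
  )
  as_tibble(vals[catalogue])
}

# Local maxima of the envelope exceeding 5x its median: a crude bout counter.
count_envelope_peaks <- function(env, k = 5) {
  if (length(env) < 3) return(0)
  thr <- k * median(env)
  mid <- env[2:(length(env) - 1)]
  sum(mid > thr & mid >= env[1:(length(env) - 2)] &
        mid >= env[3:length(env)])
}

#' Write / read a feature table as CSV
#'
#' Serializes a feature table (clip identifiers plus one column per feature)
#' to CSV with the analysis band recorded in a `#`-prefixed header comment,
#' and reads it back losslessly.
#'
#' @param features A tibble of clip identifiers and feature columns.
#' @param path CSV path.
#' @param band Numeric length-2 band bounds (Hz) recorded in the header.
#' @return `write_features()`: `path` invisibly; `read_features()`: the
#'   tibble, with a `band` attribute when the header carries one.
#' @export
write_features <- function(features, path, band = c(3000, 6000)) {
  con <- file(path, "w")
  writeLines(sprintf("# band: %g-%g Hz", band[1], band[2]), con)
  close(con)
  readr::write_csv(features, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  hdr <- readLines(path, n = 1)
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (grepl("^# band:", hdr)) {
    nums <- as.numeric(regmatches(hdr, gregexpr("[0-9.]+", hdr))[[1]])
    attr(out, "band") <- nums[1:2]
  }
  out
}
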