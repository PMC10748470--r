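#' Parameters of a synthetic cricket calling song
#'
#' Describes the signal model used by [synthesize_clip()]: a calling-song
#' bout is one long chirp followed by a train of short chirps, all carried at
#' `dominant_freq_hz` (the species' dominant frequency lies between 4 and
#' 5 kHz), embedded over incubator-like background noise (broadband Gaussian
#' plus one narrowband mains/fan hum).
#'
#' @param dominant_freq_hz Carrier frequency in Hz; must lie in
#'   `[3000, 6000]` (default 4500, mid-range of the species' 4-5 kHz band).
#' @param long_chirp_s Duration of the long chirp (s).
#' @param n_short_chirps Number of short chirps in the train.
#' @param short_chirp_s Duration of each short chirp (s).
#' @param gap_s Silent gap between chirps in a bout (s).
#' @param amplitude Master output scale in `[0, 1]`; clip RMS is linear in
#'   it (no components are driven into clipping at the defaults).
#' @param snr_db Chirp-to-broadband-noise power ratio in dB (finite).
#' @param noise_rms RMS of the broadband Gaussian noise floor (before
#'   `amplitude` scaling); 0 silences the broadband component.
#' @param hum_freq_hz Frequency of the narrowband hum component (Hz).
#' @param hum_amp Linear amplitude of the hum (before `amplitude` scaling);
#'   0 silences it.
#' @param sample_rate Samples per second; fixed at 44100 in this pipeline.
#' @return An object of class `chirp_params`.
#' @export
chirp_params <- function(dominant_freq_hz = 4500, long_chirp_s = 0.35,
                         n_short_chirps = 6, short_chirp_s = 0.12,
                         gap_s = 0.08, amplitude = 0.5, snr_db = 20,
                         noise_rms = 0.05, hum_freq_hz = 50, hum_amp = 0.02,
                         sample_rate = 44100) {
  if (dominant_freq_hz < 3000 || dominant_freq_hz > 6000) {
    stop_invalid("`dominant_freq_hz` must lie in [3000, 6000] Hz.")
  }
  if (!is.finite(snr_db)) stop_invalid("`snr_db` must be finite.")
  if (sample_rate != 44100) {
    stop_invalid("`sample_rate` is fixed at 44100 Hz in this pipeline.")
  }
  if (amplitude < 0 || amplitude > 1) {
    stop_invalid("`amplitude` must lie in [0, 1].")
  }
  structure(
    list(dominant_freq_hz = dominant_freq_hz, long_chirp_s = long_chirp_s,
         n_short_chirps = n_short_chirps, short_chirp_s = short_chirp_s,
         gap_s = gap_s, amplitude = amplitude, snr_db = snr_db,
         noise_rms = noise_rms, hum_freq_hz = hum_freq_hz, hum_amp = hum_amp,
         sample_rate = sample_rate),
    class = "chirp_params"
  )
}

# One bout: long chirp, then a train of short chirps, 5-ms cosine ramps.
chirp_bout <- function(chirp, tone_amp) {
  sr <- chirp$sample_rate
  tone <- function(dur_s) {
    n <- round(dur_s * sr)
    x <- tone_amp * sin(2 * pi * chirp$dominant_freq_hz * seq_len(n) / sr)
    ramp <- min(round(0.005 * sr), floor(n / 2))
    if (ramp > 0) {
      env <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
      x[seq_len(ramp)] <- x[seq_len(ramp)] * env
      x[n + 1 - seq_len(ramp)] <- x[n + 1 - seq_len(ramp)] * env
    }
    x
  }
  gap <- numeric(round(chirp$gap_s * sr))
  short <- tone(chirp$short_chirp_s)
  c(tone(chirp$long_chirp_s),
    unlist(rep(list(c(gap, short)), chirp$n_short_chirps), use.names = FALSE))
}

#' Synthesize a 60-second audio clip
#'
#' Produces one clip of the kind the detector scores: background noise
#' (broadband Gaussian plus a narrowband hum), with, for `state = 1`, at
#' least one calling-song bout embedded at random offsets at the configured
#' signal-to-noise ratio. Chirp amplitude is set so that the tone's RMS is
#' `snr_db` dB above the broadband noise RMS (referred to a 0.05 RMS floor
#' when `noise_rms = 0`). Output amplitudes are clamped to `[-1, 1]`.
#'
#' @param state 0 (background only) or 1 (singing present).
#' @param chirp A [chirp_params()].
#' @param duration_s Clip length in seconds (> 0; default 60, the scoring
#'   granularity of the pipeline).
#' @param seed Integer seed; identical inputs give identical samples.
#' @return Numeric vector of `duration_s * sample_rate` amplitudes.
#' @examples
#' x <- synthesize_clip(1, chirp_params(), duration_s = 2, seed = 1)
#' length(x) # 88200
#' @export
synthesize_clip <- function(state, chirp = chirp_params(), duration_s = 60,
                            seed = 1L) {
  stopifnot(inherits(chirp, "chirp_params"), state %in% c(0, 1))
  if (duration_s <= 0) stop_invalid("`duration_s` must be > 0.")
  sr <- chirp$sample_rate
  n <- round(duration_s * sr)
  withr::with_seed(seed, {
    x <- if (chirp$noise_rms > 0) rnorm(n, 0, chirp$noise_rms) else numeric(n)
    if (chirp$hum_amp > 0) {
      x <- x + chirp$hum_amp * sin(2 * pi * chirp$hum_freq_hz * seq_len(n) / sr)
    }
    if (state == 1) {
      ref_rms <- if (chirp$noise_rms > 0) chirp$noise_rms else 0.05
      tone_amp <- ref_rms * 10^(chirp$snr_db / 20) * sqrt(2)
      bout <- chirp_bout(chirp, tone_amp)
      if (length(bout) > n) bout <- bout[seq_len(n)]
      n_bouts <- max(1L, stats::rpois(1, duration_s / 10))
      starts <- sort(sample.int(max(n - length(bout), 1), n_bouts,
                                replace = TRUE))
      for (s in starts) {
        idx <- s + seq_along(bout) - 1L
        x[idx] <- x[idx] + bout
      }
    }
    pmin(pmax(chirp$amplitude * x, -1), 1)
  })
}
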