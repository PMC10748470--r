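sr <- 44100

tone_clip <- function(freq, dur = 2, amp = 1) {
  amp * sin(2 * pi * freq * seq_len(dur * sr) / sr)
}

test_that("a pure tone concentrates the band spectrum in one bin", {
  sp <- band_spectrum(tone_clip(4800), sr)
  res <- attr(sp, "resolution_hz")
  expect_lt(abs(sp$freq_hz[which.max(sp$mag)] - 4800), res + 1e-9)
  f <- compute_features(tone_clip(4800), sr)
  expect_lt(abs(f$dominant_freq_hz - 4800), res + 1e-9)
  # Hann leakage spreads a tone over ~3 bins, bounding normalized entropy
  # near ln(3)/ln(n_bins) ~ 0.15; still an order below the noise regime
  expect_lt(f$band_entropy, 0.2)
  noise <- withr::with_seed(1, rnorm(2 * sr, 0, 0.1))
  expect_lt(f$band_entropy, compute_features(noise, sr)$band_entropy / 4)
})

test_that("an all-zero clip gives a zero spectrum and convention features", {
  sp <- band_spectrum(numeric(sr), sr)
  expect_true(all(sp$mag == 0))
  f <- compute_features(numeric(sr), sr, feature_catalogue("full"))
  expect_equal(f$band_entropy, 1)    # uniform-limit convention
  expect_equal(f$band_flatness, 1)
  expect_true(is.nan(f$dominant_freq_hz))
  expect_equal(f$band_energy_ratio, 0)
})

test_that("white noise is flat in band and near-maximally entropic", {
  x <- withr::with_seed(8, rnorm(5 * sr, 0, 0.1))
  sp <- band_spectrum(x, sr)
  # Welch averaging over ~100 frames: per-bin power is a scaled chi-square
  # mean; all bins should sit well within +-50% of the band mean
  expect_true(all(sp$power > 0.5 * mean(sp$power) &
                    sp$power < 1.5 * mean(sp$power)))
  f <- compute_features(x, sr)
  expect_gt(f$band_entropy, 0.95)
})

test_that("singing clips carry more band energy than noise-only clips", {
  ch <- chirp_params(snr_db = 20)
  f1 <- compute_features(synthesize_clip(1, ch, duration_s = 5, seed = 1), sr)
  f0 <- compute_features(synthesize_clip(0, ch, duration_s = 5, seed = 1), sr)
  expect_gt(f1$band_energy_ratio, f0$band_energy_ratio)
})

test_that("features are amplitude-invariant except magnitude scale", {
  x <- synthesize_clip(1, chirp_params(), duration_s = 2, seed = 6)
  full <- feature_catalogue("full")
  fa <- compute_features(x, sr, full)
  fb <- compute_features(3 * x, sr, full)
  invariant <- c("dominant_freq_hz", "band_energy_ratio", "band_entropy",
                 "crest_factor", "band_flatness")
  for (ft in invariant) {
    expect_equal(fb[[ft]], fa[[ft]], tolerance = 1e-6, label = ft)
  }
  expect_equal(fb$band_mag_sd / fa$band_mag_sd, 3, tolerance = 1e-6)
})

test_that("the full catalogue has 19 ordered, finite descriptors", {
  full <- feature_catalogue("full")
  expect_length(full, 19)
  expect_identical(full[1:5], feature_catalogue("default"))
  x <- synthesize_clip(0, chirp_params(), duration_s = 2, seed = 2)
  f <- compute_features(x, sr, full)
  expect_identical(names(f), full)
  expect_true(all(is.finite(unlist(f))))
})

test_that("feature tables serialize losslessly to CSV and back", {
  feats <- simulate_labeled_clips(4, chirp_params(), duration_s = 2, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_features(feats, f)
  back <- read_features(f)
  expect_equal(attr(back, "band"), c(3000, 6000))
  attr(back, "band") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(feats), tolerance = 1e-12)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(compute_features(numeric(100), sr), regexp = "frame")
  expect_error(compute_features(numeric(sr), sr, catalogue = "nope"),
               class = "songclock_invalid_parameter")
  expect_error(compute_features(numeric(sr), sr, fmax = 30000),
               class = "songclock_invalid_parameter")
})

test_that("permutation-importance paring keeps the informative features", {
  data <- gaussian_feature_data(n = 200, sep = 5, seed = 4)
  kept <- pare_features(data, n_keep = 2, n_trees = 100, seed = 1)
  expect_setequal(kept, c("f1", "f2")) # f3 is pure noise
})
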