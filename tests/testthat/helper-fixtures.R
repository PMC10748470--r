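# Shared fixture builders. Everything is generated in code at test time.

# One day of minute samples tracing a triangular activity profile:
# 0 at ZT12, 1 at ZT18, 0 at ZT24, 0 elsewhere (values at minute starts).
make_triangle_series <- function() {
  zt <- (seq_len(1440) - 1) / 60
  tibble::tibble(
    id = "tri", minute = seq_len(1440) - 1L, zt = zt,
    value = pmax(0, 1 - abs(zt - 18) / 6), masked = FALSE
  )
}

# Two Gaussian feature clouds separated by `sep` SDs along the (1,1)/sqrt(2)
# direction, 50/50 classes.
gaussian_feature_data <- function(n = 400, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    label <- rep(c(0L, 1L), length.out = n)
    shift <- label * sep / sqrt(2)
    tibble::tibble(
      label = label,
      f1 = rnorm(n) + shift,
      f2 = rnorm(n) + shift,
      f3 = rnorm(n) # pure noise
    )
  })
}

# Deterministic boxcar singing series (window ZT13-ZT24) under DL.
boxcar_series <- function(days = 2, p_sing = 1, p_noise_sing = 0, seed = 1,
                          period_h = 24, regime = "DL") {
  lights_on <- if (regime == "DL") 18 else 6
  simulate_series(
    song_schedule(period_h = period_h, p_sing = p_sing,
                  p_noise_sing = p_noise_sing),
    photoschedule(regime, lights_on = lights_on),
    days = days, seed = seed
  )
}
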