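test_that("LS recovers the period of a noisy sinusoid and rejects constants", {
  t_h <- (seq_len(8 * 1440) - 1) / 60
  x <- withr::with_seed(1, sin(2 * pi * t_h / 24) + rnorm(length(t_h), 0, 0.3))
  pg <- lomb_scargle(tibble::tibble(t_h = t_h, value = x))
  expect_true(pg$is_rhythmic)
  expect_lt(abs(pg$best_period - 24), 0.1)

  const <- tibble::tibble(t_h = t_h, value = 1)
  pgc <- lomb_scargle(const)
  expect_false(pgc$is_rhythmic)
  expect_true(all(pgc$spectrum$power == 0))
  expect_true(is.na(pgc$best_period))
})

test_that("LS recovers the simulator's free-running period", {
  s <- simulate_series(song_schedule(period_h = 25.1, p_sing = 0.8),
                       photoschedule("DD"), days = 8, seed = 3)
  pg <- lomb_scargle(s)
  expect_lt(abs(pg$best_period - 25.1), 0.2)
})

test_that("LS demands three cycles of data and honours the mask", {
  short <- boxcar_series(days = 3)
  expect_error(lomb_scargle(short), class = "songclock_invalid_parameter")
  s <- boxcar_series(days = 8, p_sing = 0.9, seed = 2)
  s$masked[1:1440] <- TRUE
  expect_lt(abs(lomb_scargle(s)$best_period - 24), 0.1)
})

test_that("the significance threshold has its closed form", {
  expect_equal(ls_significance_threshold(0.05, 1), -log(0.05))
  # independent evaluation: solve P(max of M unit exponentials > z) = alpha
  for (m in c(10, 100)) {
    z_root <- uniroot(function(z) 1 - (1 - exp(-z))^m - 0.05, c(0.1, 50),
                      tol = 1e-12)$root
    expect_equal(ls_significance_threshold(0.05, m), z_root, tolerance = 1e-9)
  }
  # monotone increasing as alpha shrinks
  alphas <- c(0.2, 0.05, 0.01, 1e-4)
  expect_true(all(diff(sapply(alphas, ls_significance_threshold, m = 20)) > 0))
})

test_that("LS power equals the brute-force least-squares reduction", {
  # oracle: per-frequency sinusoid regression on the centred data
  ls_oracle <- function(t, x, periods) {
    xc <- x - mean(x)
    sigma2 <- sum(xc^2) / (length(x) - 1)
    sapply(periods, function(p) {
      w <- 2 * pi / p
      fit <- lm(xc ~ 0 + cos(w * t) + sin(w * t))
      (sum(xc^2) - sum(residuals(fit)^2)) / (2 * sigma2)
    })
  }
  withr::with_seed(4, {
    t_reg <- seq(0, 96, length.out = 512)
    x <- sin(2 * pi * t_reg / 25) + rnorm(512, 0, 0.5)
    keep <- sort(sample(512, 400)) # irregular sampling
  })
  for (case in list(list(t = t_reg, x = x),
                    list(t = t_reg[keep], x = x[keep]))) {
    pg <- lomb_scargle(tibble::tibble(t_h = case$t, value = case$x),
                       period_range = c(18, 30), period_step = 0.5)
    expect_lt(max(abs(pg$spectrum$power -
                        ls_oracle(case$t, case$x, pg$spectrum$period_h))),
              1e-8)
  }
})

test_that("phase markers hit the 20%-of-peak crossings of a triangle", {
  mk <- phase_markers(make_triangle_series(), bin_min = 1, smooth_bins = 1)
  expect_equal(mk$onset_zt, 13.2)
  expect_equal(mk$peak_zt, 18.0)
  expect_equal(mk$offset_zt, 22.8)
})

test_that("boxcar windows give edge markers and zero days give none", {
  s <- boxcar_series(days = 2)
  mk <- phase_markers(s, bin_min = 1, smooth_bins = 1)
  expect_equal(mk$onset_zt, rep(13, 2), tolerance = 0.02)
  expect_true(all(mk$peak_zt >= 13 & mk$peak_zt < 24))
  # offset at the end of the day: compare circularly to ZT24
  expect_true(all(abs((mk$offset_zt - 24) %% 24) < 0.02 |
                    abs(24 - (mk$offset_zt - 24) %% 24) < 0.02))

  z <- s; z$value <- 0L
  mz <- phase_markers(z)
  expect_true(all(is.na(mz$onset_zt) & is.na(mz$peak_zt) &
                    is.na(mz$offset_zt)))
})

test_that("noise-free recovery stays within half a bin plus smoothing", {
  s <- boxcar_series(days = 4)
  mk <- phase_markers(s, bin_min = 30, smooth_bins = 3)
  tol <- 0.25 + 0.5 # half bin + smoothing half-window, hours
  expect_true(all(abs(mk$onset_zt - 13) <= tol))
  expect_true(all(abs((mk$offset_zt - 24) %% 24) <= tol |
                    (24 - (mk$offset_zt - 24) %% 24) <= tol))
})

test_that("circular statistics obey their identities", {
  expect_equal(circular_mean(c(23, 1)), 0)
  expect_equal(angular_variance(c(7.3, 7.3, 7.3)), 0)
  expect_equal(mean_resultant_length(c(0, 6, 12, 18)), 0, tolerance = 1e-12)
  expect_equal(angular_variance(c(0, 6, 12, 18)), 1, tolerance = 1e-12)

  withr::with_seed(5, {
    for (i in 1:5) {
      h <- runif(20, 0, 24)
      off <- runif(1, -30, 30)
      m0 <- circular_mean(h)
      expect_lt(abs(songclock:::circular_diff((m0 + off) %% 24,
                                              circular_mean(h + off))), 1e-9)
      expect_lt(abs(angular_variance(h) - angular_variance(h + off)), 1e-9)
    }
  })
})

test_that("phase shifts are signed shortest arcs with a permutation p", {
  # group means like the entrained-vs-reversed onset contrast
  expect_equal(phase_shift(13.24, 12.34, n_perm = 10)$shift_h, 0.90)
  same <- phase_shift(c(13, 14, 15), c(13, 14, 15), n_perm = 200, seed = 1)
  expect_equal(same$shift_h, 0)
  expect_gt(same$p_value, 0.9)
  expect_equal(phase_shift(23.5, 0.5, n_perm = 10)$shift_h, -1.0) # delay
  expect_error(phase_shift(numeric(0), 1), class = "songclock_invalid_parameter")
})

test_that("period summaries aggregate by group with a pooled row", {
  df <- tibble::tibble(best_period = c(25, 25, 25, 25),
                       group = c("a", "a", "b", "b"))
  ps <- period_summary(df)
  expect_equal(ps$mean_period_h, rep(25, 3))
  expect_equal(ps$se_period_h[1:2], c(0, 0))
  single <- period_summary(tibble::tibble(best_period = 24.5, group = "x"))
  expect_true(is.na(single$se_period_h[1]))
})

test_that("the period permutation test separates real group differences", {
  same <- period_permutation_test(rep(c(25.1, 25.12, 25.08), 3),
                                  rep(c("a", "b", "c"), each = 3),
                                  n_perm = 500, seed = 1)
  expect_gt(same$p_value, 0.05)
  # groups of 5 so label permutations can resolve a 5% tail (C(10,5) = 252)
  diffg <- period_permutation_test(
    c(24, 24.1, 24, 24.05, 24.02, 26, 26.1, 26, 26.05, 26.02),
    rep(c("a", "b"), each = 5), n_perm = 2000, seed = 1)
  expect_lt(diffg$p_value, 0.05)
})
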