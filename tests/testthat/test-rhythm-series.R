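test_that("clip predictions map 1:1 onto minutes, with gaps masked", {
  sched <- photoschedule("LD")
  pred <- tibble::tibble(minute = 0:2, prediction = c(1, 0, 1))
  s <- binarize_scores(pred, sched)
  expect_equal(s$value, c(1L, 0L, 1L))
  expect_false(any(s$masked))

  # a 24-h equipment gap masks 1440 minutes and nothing else
  pred2 <- tibble::tibble(minute = c(0:1439, 2880:4319),
                          prediction = rep(1L, 2880))
  s2 <- binarize_scores(pred2, sched)
  expect_equal(sum(s2$masked), 1440)
  expect_equal(singing_effort(s2), 24) # unaffected by the masked day

  expect_warning(s3 <- binarize_scores(pred[0, ], sched), regexp = "empty")
  expect_equal(nrow(s3), 0)
})

test_that("acclimation and post-reversal trims mask the stated spans", {
  s <- boxcar_series(days = 8)
  tr <- trim_days(s)
  expect_equal(length(unique(tr$minute[!tr$masked] %/% 1440)), 5)
  expect_true(all(tr$masked[tr$t_h < 72]))

  e3 <- simulate_series(song_schedule(p_sing = 1, p_noise_sing = 0),
                        photoschedule("LD", reversal_day = 9), days = 15,
                        seed = 1)
  tr3 <- trim_days(e3)
  d <- tr3$minute %/% 1440
  expect_true(all(tr3$masked[d %in% 9:12]))
  expect_false(any(tr3$masked[d %in% 13:14]))

  short <- boxcar_series(days = 2)
  expect_error(trim_days(short), class = "songclock_invalid_parameter")
})

test_that("singing effort conserves total singing minutes", {
  s <- boxcar_series(days = 1, p_sing = 1)
  all_on <- s; all_on$value <- 1L
  expect_equal(singing_effort(all_on), 24)
  expect_equal(singing_effort(boxcar_series(days = 3)), 11) # 660 min/day

  r <- boxcar_series(days = 5, p_sing = 0.7, seed = 42)
  days <- length(unique(r$minute %/% 1440))
  expect_equal(singing_effort(r) * days * 60, sum(r$value))

  masked_all <- s; masked_all$masked <- TRUE
  expect_error(singing_effort(masked_all), class = "songclock_invalid_parameter")
})

test_that("dark/light singing fractions follow the schedule", {
  s <- boxcar_series(days = 2)
  s$value <- as.integer(s$phase == "dark") # sings the whole dark phase
  pf <- phase_activity_fraction(s)
  expect_equal(pf$dark_fraction, 1)
  expect_equal(pf$light_fraction, 0)

  z <- s; z$value <- 0L
  expect_equal(unlist(phase_activity_fraction(z)),
               c(dark_fraction = 0, light_fraction = 0))

  # binomial oracle: window ZT13-24 at p_sing = 0.68 over 5 days means the
  # dark-phase fraction is (660/720) * 0.68 within the 95% binomial band
  sim <- boxcar_series(days = 5, p_sing = 0.68, seed = 10)
  p_expect <- 0.68 * 660 / 720
  n_dark <- 5 * 720
  band <- 1.96 * sqrt(p_expect * (1 - p_expect) / n_dark)
  expect_lt(abs(phase_activity_fraction(sim)$dark_fraction - p_expect), band * 1.5)
})

test_that("group averaging is a per-minute masked mean", {
  sched <- photoschedule("LD")
  mk <- function(v, mask = FALSE) {
    binarize_scores(tibble::tibble(minute = seq_along(v) - 1L, prediction = v),
                    sched)
  }
  a <- mk(c(1, 1, 0)); b <- mk(c(1, 0, 0))
  g <- average_group(list(a, b))
  expect_equal(g$value, c(1, 0.5, 0))

  bm <- b; bm$masked <- TRUE
  g2 <- average_group(list(a, bm))
  expect_equal(g2$value, a$value) # fully masked member drops out
  expect_identical(average_group(list(a))$value, as.numeric(a$value))

  # bounds: group average sits within member min/max each minute
  s1 <- boxcar_series(days = 2, p_sing = 0.6, seed = 1)
  s2 <- boxcar_series(days = 2, p_sing = 0.9, seed = 2)
  g3 <- average_group(list(s1, s2))
  expect_true(all(g3$value >= pmin(s1$value, s2$value) &
                    g3$value <= pmax(s1$value, s2$value)))
})

test_that("actograms satisfy the double-plot identity", {
  s <- boxcar_series(days = 3)
  a <- build_actogram(s)
  expect_equal(dim(unclass(a)), c(2, 2880))
  for (sd in 1:3) {
    r <- build_actogram(boxcar_series(days = 4, p_sing = 0.5, seed = sd))
    m <- unclass(r)
    for (d in seq_len(nrow(m) - 1)) {
      expect_identical(m[d, 1441:2880], m[d + 1, 1:1440])
    }
  }
  const <- s; const$value <- 1L
  expect_true(all(unclass(build_actogram(const)) == 1))
})

test_that("polar profiles wrap activity into 48 ZT bins", {
  s <- boxcar_series(days = 3)
  pp <- polar_profile(s)
  expect_equal(nrow(pp), 48)
  in_window <- pp$zt >= 13 & pp$zt < 24
  expect_true(all(pp$value[in_window] == 1))
  expect_true(all(pp$value[!in_window] == 0))
  const <- s; const$value <- 1L
  expect_true(all(polar_profile(const)$value == 1))
  expect_error(polar_profile(s, bin_min = 7), class = "songclock_invalid_parameter")
})
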