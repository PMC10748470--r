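#' Parameters of a circadian singing schedule
#'
#' Describes the nightly singing programme of one simulated cricket: an
#' endogenous oscillator of period `period_h` gates a singing window, inside
#' which each minute carries probability `p_sing` of at least one song and
#' outside which probability `p_noise_sing` (sporadic daytime chirps).
#' Defaults emulate the nocturnal singing of *Teleogryllus oceanicus*:
#' a window from about one hour after lights-off (ZT13) to the end of the
#' dark phase (ZT24), matching the observed mean onset near ZT13 and offset
#' near ZT24 under entrained conditions.
#'
#' @param period_h Free-running / entrained period tau in hours, in
#'   `[18, 30]`. Expressed only under constant darkness; under LD or DL the
#'   rhythm is entrained to the 24-h photoschedule.
#' @param onset_zt,offset_zt Singing-window bounds in ZT hours (circular; a
#'   value of 24 is accepted as the end of the day). Window width is
#'   `(offset_zt - onset_zt) mod 24`; equal bounds mean the full day.
#' @param p_sing Per-minute probability of singing inside the window.
#' @param p_noise_sing Per-minute probability of singing outside the window;
#'   must not exceed `p_sing`.
#' @param profile `"boxcar"` for a flat window, `"bump"` for a smoothed
#'   raised-cosine nightly profile peaking mid-window (same bounds at the
#'   20%-of-peak level cannot be guaranteed for `"bump"`; it trades sharp
#'   edges for a more realistic ramp-up/ramp-down).
#'
#' @return An object of class `song_schedule`.
#' @examples
#' song_schedule(period_h = 25.1, p_sing = 0.8)
#' @export
song_schedule <- function(period_h = 24, onset_zt = 13, offset_zt = 24,
                          p_sing = 0.8, p_noise_sing = 0.01,
                          profile = c("boxcar", "bump")) {
  profile <- match.arg(profile)
  if (period_h < 18 || period_h > 30) {
    stop_invalid("`period_h` must lie in [18, 30] h (got ", period_h, ").")
  }
  for (b in c(onset_zt, offset_zt)) {
    if (!is.numeric(b) || b < 0 || b > 24) {
      stop_invalid("window bounds must be ZT hours in [0, 24].")
    }
  }
  if (p_noise_sing < 0 || p_sing > 1 || p_noise_sing > p_sing) {
    stop_invalid("need 0 <= p_noise_sing <= p_sing <= 1.")
  }
  structure(
    list(period_h = period_h, onset_zt = onset_zt %% 24,
         offset_zt = offset_zt, p_sing = p_sing,
         p_noise_sing = p_noise_sing, profile = profile),
    class = "song_schedule"
  )
}

window_width_h <- function(params) {
  w <- (params$offset_zt - params$onset_zt) %% 24
  if (w == 0) 24 else w
}

# Per-minute singing probability at elapsed hours t_h (vectorised).
# Under DD the window is gated by the free-running oscillator, so the
# expressed period is exactly `period_h` and consecutive onsets drift by
# (period_h - 24) h per cycle. Under LD/DL the window is anchored to ZT
# (entrained); across an LD -> DL reversal the anchor delays linearly over
# `transient_days` days until re-aligned with the new lights-off.
schedule_probability <- function(params, sched, t_h, transient_days = 4) {
  w <- window_width_h(params)
  if (sched$regime == "DD") {
    ph <- (t_h - params$onset_zt) %% params$period_h
  } else {
    zt <- zt_at(sched, t_h)
    onset <- params$onset_zt
    if (!is.null(sched$reversal_day)) {
      d <- floor(t_h / 24)
      j <- d - sched$reversal_day
      post <- j >= 0
      # remaining phase lag relative to the reversed schedule, delaying to 0
      lag <- ifelse(post, 12 * pmax(0, 1 - j / max(transient_days, 1)), 0)
      onset <- (params$onset_zt + lag) %% 24
    }
    ph <- (zt - onset) %% 24
  }
  inside <- ph < w
  if (params$profile == "boxcar") {
    if_else(inside, params$p_sing, params$p_noise_sing)
  } else {
    # raised-cosine bump over the window, peak probability p_sing mid-window
    shape <- 0.5 * (1 - cos(2 * pi * ph / w))
    if_else(inside,
            pmax(params$p_noise_sing, params$p_sing * shape),
            params$p_noise_sing)
  }
}

new_singing_series <- function(tbl, sched, start) {
  structure(tbl, class = c("singing_series", class(tibble())),
            photoschedule = sched, start = start)
}

#' Simulate a ground-truth per-minute singing series
#'
#' Generates one individual's per-minute singing record (one binary state per
#' elapsed minute, no gaps) under a photoschedule. Singing minutes are drawn
#' Bernoulli with the window-dependent probability of the schedule (see
#' [song_schedule()]); with `p_sing = 1` and `p_noise_sing = 0` the series is
#' the deterministic window indicator. The series starts at ZT0 (lights-on)
#' of day 0.
#'
#' @param params A [song_schedule()].
#' @param sched A [photoschedule()].
#' @param days Number of 24-h days to simulate (>= 1).
#' @param seed Integer seed; identical `(params, sched, days, seed)` give
#'   identical series.
#' @param id Individual identifier stored in the `id` column.
#' @param start Start datetime (`POSIXct`, taken as the first lights-on).
#' @param transient_days Days of linear phase adjustment after an LD -> DL
#'   reversal (see [song_schedule()] details); default 4, the span discarded
#'   as transient cycles in analysis.
#'
#' @return A `singing_series` tibble with one row per minute and columns
#'   `id`, `minute` (0-based), `datetime`, `t_h` (elapsed hours), `zt`,
#'   `phase`, `regime`, `value` (0/1) and `masked` (all `FALSE`).
#' @examples
#' s <- simulate_series(song_schedule(p_sing = 1, p_noise_sing = 0),
#'                      photoschedule("DL", lights_on = 18), days = 1, seed = 1)
#' sum(s$value) # 660 = 11 h x 60 min
#' @export
simulate_series <- function(params, sched, days, seed = 1L, id = "sim",
                            start = as.POSIXct("2023-01-01 00:00:00",
                                               tz = "UTC"),
                            transient_days = 4) {
  stopifnot(inherits(params, "song_schedule"), inherits(sched, "photoschedule"))
  if (!is.numeric(days) || days < 1 || days != round(days)) {
    stop_invalid("`days` must be a whole number >= 1.")
  }
  n <- as.integer(days * 1440)
  minute <- seq_len(n) - 1L
  t_h <- minute / 60
  p <- schedule_probability(params, sched, t_h, transient_days)
  value <- withr::with_seed(seed, as.integer(runif(n) < p))
  start <- start + (sched$lights_on * 3600) # align datetime to lights-on
  tbl <- tibble(
    id = id, minute = minute,
    datetime = start + minute * 60,
    t_h = t_h,
    zt = zt_at(sched, t_h),
    phase = phase_at(sched, t_h),
    regime = regime_at(sched, t_h),
    value = value,
    masked = FALSE
  )
  new_singing_series(tbl, sched, start)
}
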