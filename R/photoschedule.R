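#' Define a photoschedule
#'
#' A photoschedule describes the lighting regime an individual experiences
#' during recording: a standard 12:12 light:dark cycle (`"LD"`), the reversed
#' cycle (`"DL"`), or constant darkness (`"DD"`). Zeitgeber time (ZT) is
#' referenced to lights-on: ZT0 is the start of the (subjective) light phase
#' and, under 12:12, ZT12 is lights-off. For `"DD"` the schedule has no light
#' transitions but retains `lights_on` from the pre-DD rearing schedule so
#' that *subjective* day and night can still be assigned.
#'
#' An LD-to-DL reversal experiment is encoded with `regime = "LD"` plus a
#' `reversal_day`: at lights-on (ZT0) of that day the incubator switches to
#' the reversed photoperiod, i.e. lights-on moves 12 h. After the switch, ZT
#' is referenced to the *new* regime's lights-on, so the DL dark phase spans
#' ZT12-ZT24 of the new schedule.
#'
#' @param regime One of `"LD"`, `"DL"`, `"DD"`.
#' @param lights_on Clock time of lights-on in hours, in `[0, 24)`. For
#'   `"DL"` this is the (reversed) lights-on actually experienced; for `"DD"`
#'   it is the prior entrainment schedule used for subjective phases.
#' @param reversal_day Optional 0-based day index at which an LD schedule
#'   switches to DL (at ZT0 of that day). Only valid with `regime = "LD"`.
#' @param temperature_c Temperature label in degrees Celsius (metadata only;
#'   the study used 22, 25 and 28).
#'
#' @return An object of class `photoschedule` (a named list).
#' @examples
#' photoschedule("LD", lights_on = 6)
#' photoschedule("LD", lights_on = 6, reversal_day = 9) # LD -> DL at day 9
#' photoschedule("DD", lights_on = 6, temperature_c = 28)
#' @export
photoschedule <- function(regime = c("LD", "DL", "DD"), lights_on = 6,
                          reversal_day = NULL, temperature_c = 25) {
  regime <- match.arg(regime)
  if (!is.numeric(lights_on) || length(lights_on) != 1 ||
      lights_on < 0 || lights_on >= 24) {
    stop_invalid("`lights_on` must be a single hour in [0, 24).")
  }
  if (!is.null(reversal_day)) {
    if (regime != "LD") {
      stop_invalid("`reversal_day` is only valid for an LD -> DL transition ",
                   "(regime must be \"LD\").")
    }
    if (!is.numeric(reversal_day) || length(reversal_day) != 1 ||
        reversal_day < 1 || reversal_day != round(reversal_day)) {
      stop_invalid("`reversal_day` must be a positive whole day index.")
    }
  }
  structure(
    list(regime = regime, lights_on = lights_on, cycle_h = 24,
         reversal_day = reversal_day, temperature_c = temperature_c),
    class = "photoschedule"
  )
}

#' @export
print.photoschedule <- function(x, ...) {
  cat("<photoschedule> ", x$regime,
      if (!is.null(x$reversal_day)) sprintf(" -> DL at day %d", x$reversal_day),
      sprintf(" | lights-on %05.2f h | %g degC\n",
              x$lights_on, x$temperature_c), sep = "")
  invisible(x)
}

# Regime actually in force at elapsed hour t (t = 0 is ZT0 of day 0).
regime_at <- function(sched, t_h) {
  out <- rep(sched$regime, length(t_h))
  if (!is.null(sched$reversal_day)) {
    out[t_h >= sched$reversal_day * 24] <- "DL"
  }
  out
}

# Clock time (h of day) at elapsed hour t. Day 0 starts at lights-on of the
# initial regime, i.e. elapsed time 0 corresponds to clock `lights_on`.
clock_at <- function(sched, t_h) {
  (sched$lights_on + t_h) %% 24
}

#' Zeitgeber time at elapsed experiment time
#'
#' Converts elapsed time (hours since the experiment's first lights-on) to
#' Zeitgeber time under a photoschedule, honouring an LD -> DL reversal: after
#' the switch, ZT is referenced to the new regime's lights-on (which moves by
#' 12 h), so the reversal instant itself is ZT0 of the new schedule.
#'
#' @param sched A [photoschedule()].
#' @param t_h Numeric vector of elapsed hours (0 = ZT0 of day 0).
#' @return Numeric vector of ZT hours in `[0, 24)`.
#' @examples
#' zt_at(photoschedule("LD", 6), c(0, 13, 25))
#' @export
zt_at <- function(sched, t_h) {
  reg <- regime_at(sched, t_h)
  zt <- t_h %% 24
  # after reversal lights-on moves 12 h later, so ZT drops back by 12
  zt[reg != sched$regime] <- (zt[reg != sched$regime] - 12) %% 24
  zt
}

#' Light / dark phase at elapsed experiment time
#'
#' Assigns each elapsed time the phase of the photoschedule in force there:
#' `"light"`/`"dark"` under LD or DL, and `"subjective_light"`/
#' `"subjective_dark"` under DD (carried from the prior entrainment schedule,
#' the grey-bar convention of actograms).
#'
#' @inheritParams zt_at
#' @return Character vector of phase labels.
#' @export
phase_at <- function(sched, t_h) {
  zt <- zt_at(sched, t_h)
  light <- zt < 12
  if (sched$regime == "DD") {
    if_else(light, "subjective_light", "subjective_dark")
  } else {
    if_else(light, "light", "dark")
  }
}
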