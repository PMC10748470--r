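#' Protocols of the three incubator experiments
#'
#' Builders for the three standard experimental designs, each describing a
#' set of individuals with their photoschedules and singing-schedule
#' parameters:
#'
#' * **Experiment 1** — photoperiod-reversed entrainment: individuals
#'   recorded under DL at 25 degC (default n = 4, 8 days), to verify
#'   nocturnal singing and estimate the entrained period.
#' * **Experiment 2** — free run: individuals in constant darkness at 22,
#'   25 or 28 degC (default n = 5/4/5, 8 days), to estimate free-running
#'   periods and probe temperature compensation.
#' * **Experiment 3** — entrainment after reversal: LD for 9 days then DL
#'   (switch at lights-on, ZT0, of day 9) at 22/25/28 degC (default
#'   n = 8/6/8, 17 days), to study re-entrainment and phase shifts.
#'
#' Between-individual variation enters through Gaussian jitter of the
#' window onset (`onset_sd_h`) and, under DD, of the free-running period
#' (`period_sd_h`), reproducibly derived from `seed`.
#'
#' @param n,n_per_temp Individuals (experiment 1) or named per-temperature
#'   counts (experiments 2 and 3).
#' @param days Recording days per individual.
#' @param period_h Mean oscillator period (h): 24 when entrained, ~25.1
#'   free-running.
#' @param params Baseline [song_schedule()] whose window/probabilities all
#'   individuals share before jitter.
#' @param onset_sd_h,period_sd_h Between-individual SDs.
#' @param lights_on Rearing lights-on clock hour (6 in the source colony;
#'   DL schedules use its 12-h reversal).
#' @param reversal_day Day of the LD -> DL switch (experiment 3).
#' @return An `experiment_protocol`: tibble with one row per individual
#'   (`individual_id`, `temperature_c`, `days`, list-columns `sched`,
#'   `params`) plus attributes.
#' @name protocols
NULL

new_protocol <- function(tbl, experiment) {
  structure(tbl, class = c("experiment_protocol", class(tibble())),
            experiment = experiment)
}

#' @rdname protocols
#' @export
protocol_experiment1 <- function(n = 4, days = 8, params = song_schedule(),
                                 onset_sd_h = 1, lights_on = 6, seed = 1L) {
  jit <- withr::with_seed(seed, rnorm(n, 0, onset_sd_h))
  tbl <- tibble(
    individual_id = sprintf("e1_c%02d", seq_len(n)),
    temperature_c = 25, days = days,
    sched = lapply(seq_len(n), function(i) {
      photoschedule("DL", lights_on = (lights_on + 12) %% 24,
                    temperature_c = 25)
    }),
    params = lapply(seq_len(n), function(i) {
      p <- params
      p$onset_zt <- (p$onset_zt + jit[i]) %% 24
      p$offset_zt <- (p$offset_zt + jit[i]) %% 24
      p$period_h <- 24
      p
    })
  )
  new_protocol(tbl, 1L)
}

#' @rdname protocols
#' @export
protocol_experiment2 <- function(n_per_temp = c("22" = 5, "25" = 4, "28" = 5),
                                 days = 8, period_h = 25.1,
                                 period_sd_h = 0.25, onset_sd_h = 1,
                                 params = song_schedule(),
                                 lights_on = 6, seed = 1L) {
  temps <- rep(as.numeric(names(n_per_temp)), n_per_temp)
  n <- length(temps)
  draws <- withr::with_seed(seed, {
    list(tau = rnorm(n, period_h, period_sd_h),
         jit = rnorm(n, 0, onset_sd_h))
  })
  tbl <- tibble(
    individual_id = sprintf("e2_c%02d", seq_len(n)),
    temperature_c = temps, days = days,
    sched = lapply(seq_len(n), function(i) {
      photoschedule("DD", lights_on = lights_on, temperature_c = temps[i])
    }),
    params = lapply(seq_len(n), function(i) {
      p <- params
      p$onset_zt <- (p$onset_zt + draws$jit[i]) %% 24
      p$offset_zt <- (p$offset_zt + draws$jit[i]) %% 24
      p$period_h <- min(30, max(18, draws$tau[i]))
      p
    })
  )
  new_protocol(tbl, 2L)
}

#' @rdname protocols
#' @export
protocol_experiment3 <- function(n_per_temp = c("22" = 8, "25" = 6, "28" = 8),
                                 days = 17, reversal_day = 9,
                                 onset_sd_h = 1, params = song_schedule(),
                                 lights_on = 6, seed = 1L) {
  temps <- rep(as.numeric(names(n_per_temp)), n_per_temp)
  n <- length(temps)
  jit <- withr::with_seed(seed, rnorm(n, 0, onset_sd_h))
  tbl <- tibble(
    individual_id = sprintf("e3_c%02d", seq_len(n)),
    temperature_c = temps, days = days,
    sched = lapply(seq_len(n), function(i) {
      photoschedule("LD", lights_on = lights_on, reversal_day = reversal_day,
                    temperature_c = temps[i])
    }),
    params = lapply(seq_len(n), function(i) {
      p <- params
      p$onset_zt <- (p$onset_zt + jit[i]) %% 24
      p$offset_zt <- (p$offset_zt + jit[i]) %% 24
      p$period_h <- 24
      p
    })
  )
  new_protocol(tbl, 3L)
}

#' Simulate a whole experiment
#'
#' Runs [simulate_series()] for every individual of a protocol and
#' (optionally) writes the files the ingest and rhythm stages consume:
#' a per-minute ground-truth CSV (`individual_id, datetime, minute_index,
#' singing`), a metadata CSV (`file, individual_id, start_datetime, regime,
#' lights_on, temperature_c, incubator`; one row per regime segment, so an
#' LD -> DL protocol's regime column switches exactly at the reversal-day
#' lights-on), and, in audio mode, a bounded number of 60-s WAV clips per
#' individual with their true labels. Series-only mode is the default:
#' eight days of 44.1-kHz audio per cricket is far beyond desk scale, and
#' the circadian stages only need the per-minute series.
#'
#' @param protocol An `experiment_protocol`.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing and just returns the simulated objects.
#' @param mode `"series"` (default) or `"audio"`.
#' @param seed Master integer seed; per-individual seeds derive from it.
#' @param clips_per_individual WAV clips emitted per individual in audio
#'   mode (sampled evenly across each individual's minutes).
#' @param chirp [chirp_params()] for audio mode.
#' @param start First lights-on datetime.
#' @return List with `series` (named list of `singing_series`), `truth`,
#'   `metadata` (tibbles) and `files` (paths written, if any).
#' @export
simulate_experiment <- function(protocol, out_dir = NULL,
                                mode = c("series", "audio"), seed = 1L,
                                clips_per_individual = 10,
                                chirp = chirp_params(),
                                start = as.POSIXct("2023-01-01 00:00:00",
                                                   tz = "UTC")) {
  mode <- match.arg(mode)
  stopifnot(inherits(protocol, "experiment_protocol"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  n <- nrow(protocol)
  series <- vector("list", n)
  names(series) <- protocol$individual_id
  meta <- vector("list", n)
  files <- character()
  for (i in seq_len(n)) {
    id <- protocol$individual_id[i]
    sched <- protocol$sched[[i]]
    series[[i]] <- simulate_series(protocol$params[[i]], sched,
                                   days = protocol$days[i],
                                   seed = seed + 1000L * i, id = id,
                                   start = start)
    seg_start <- start + sched$lights_on * 3600
    if (is.null(sched$reversal_day)) {
      meta[[i]] <- tibble(file = paste0(id, "_series.csv"),
                          individual_id = id,
                          start_datetime = format_iso(seg_start),
                          regime = sched$regime, lights_on = sched$lights_on,
                          temperature_c = protocol$temperature_c[i],
                          incubator = "sim")
    } else {
      rev_t <- seg_start + sched$reversal_day * 86400
      meta[[i]] <- tibble(
        file = paste0(id, c("_ld_series.csv", "_dl_series.csv")),
        individual_id = id,
        start_datetime = format_iso(c(seg_start, rev_t)),
        regime = c("LD", "DL"),
        lights_on = c(sched$lights_on, (sched$lights_on + 12) %% 24),
        temperature_c = protocol$temperature_c[i], incubator = "sim")
    }
  }
  truth <- bind_rows(lapply(series, function(s) {
    tibble(individual_id = s$id, datetime = format_iso(s$datetime),
           minute_index = s$minute, singing = s$value)
  }))
  metadata <- bind_rows(meta)
  if (mode == "audio" && !is.null(out_dir)) {
    wav_meta <- vector("list", n)
    for (i in seq_len(n)) {
      s <- series[[i]]
      pick <- unique(round(seq(1, nrow(s), length.out = clips_per_individual)))
      paths <- file.path(out_dir, sprintf("%s_clip%04d.wav",
                                          protocol$individual_id[i],
                                          s$minute[pick]))
      for (j in seq_along(pick)) {
        x <- synthesize_clip(s$value[pick[j]], chirp,
                             seed = seed + 7L * i + 131L * j)
        write_wav(x, paths[j], chirp$sample_rate)
      }
      wav_meta[[i]] <- meta[[i]][rep(1, length(pick)), ] %>%
        mutate(file = basename(paths),
               start_datetime = format_iso(s$datetime[pick]),
               regime = s$regime[pick])
      files <- c(files, paths)
    }
    metadata <- bind_rows(wav_meta)
  }
  if (!is.null(out_dir)) {
    truth_path <- file.path(out_dir, "ground_truth.csv")
    meta_path <- file.path(out_dir, "metadata.csv")
    readr::write_csv(truth, truth_path)
    readr::write_csv(metadata, meta_path)
    files <- c(files, truth_path, meta_path)
  }
  list(series = series, truth = truth, metadata = metadata, files = files)
}

format_iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Synthesize a labeled clip set and featurize it
#'
#' Convenience generator for classifier experiments: synthesizes `n`
#' clips (a balanced mix of singing and background unless
#' `singing_fraction` says otherwise), computes the requested feature
#' catalogue for each, and returns the labeled feature table ready for
#' [cross_validate()] or [split_train_validation()].
#'
#' @param n Number of clips.
#' @param chirp [chirp_params()] for synthesis.
#' @param duration_s Clip duration (s).
#' @param singing_fraction Fraction of clips with singing.
#' @param catalogue Feature names (see [feature_catalogue()]).
#' @param seed Integer seed.
#' @return Tibble with `clip_id`, `label` and one column per feature.
#' @export
simulate_labeled_clips <- function(n, chirp = chirp_params(),
                                   duration_s = 60, singing_fraction = 0.5,
                                   catalogue = feature_catalogue("default"),
                                   seed = 1L) {
  n_sing <- round(n * singing_fraction)
  labels <- withr::with_seed(seed, sample(rep(c(1L, 0L),
                                              c(n_sing, n - n_sing))))
  rows <- lapply(seq_len(n), function(i) {
    x <- synthesize_clip(labels[i], chirp, duration_s = duration_s,
                         seed = seed + i)
    compute_features(x, chirp$sample_rate, catalogue = catalogue)
  })
  bind_rows(rows) %>%
    mutate(clip_id = sprintf("clip%04d", seq_len(n)), label = labels) %>%
    select("clip_id", "label", dplyr::everything())
}
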