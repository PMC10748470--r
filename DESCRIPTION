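Package: songclock
Title: Audio-to-Circadian Analysis of Cricket Singing Rhythms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An audio-to-circadian pipeline for quantifying the daily singing
    rhythms of field crickets from continuous incubator recordings. Detects
    calling song in consecutive 60-second audio clips via band-limited
    spectral descriptors and a cross-validated random-forest classifier,
    converts per-clip detections into per-minute behavioural time series
    anchored to Zeitgeber time, and characterises their circadian properties:
    Lomb-Scargle period estimation with significance testing, daily phase
    markers (onset, peak, offset) by the 20-percent-of-peak rule, circular
    summaries (circular mean, angular variance), phase-shift quantification
    across photoschedule reversals, actograms and polar activity profiles.
    Includes a synthetic song and experiment simulator (parametric circadian
    singing schedules, chirp synthesis over incubator-like noise, and the
    standard LD/DD/LD-to-DL protocols) so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    utils,
    withr
Suggests:
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
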