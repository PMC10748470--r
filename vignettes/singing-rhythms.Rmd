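---
title: "From audio to circadian parameters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From audio to circadian parameters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songclock)
library(dplyr)
```

songclock turns continuous incubator recordings of a singing insect into
circadian parameters. The pipeline has five stages — synthesis/ground truth,
audio ingest, spectral features, a song classifier, and circadian analysis —
and this vignette explains the model behind each stage, the tunable
parameters that matter, and the design decisions taken where the problem was
genuinely open.

## The behavioural model

The organism of interest is a nocturnally singing field cricket
(*Teleogryllus oceanicus*-like): males stridulate mostly during the dark
phase, with a calling song carried at a dominant frequency between 4 and
5 kHz, structured as a long chirp followed by a train of short chirps.
Singing is scored at one-minute resolution as a binary state — "the animal
sang at least once during this minute" — which makes the behavioural record
a per-minute 0/1 time series anchored to Zeitgeber time (ZT; hours since
lights-on, so ZT12 is lights-off under a 12:12 photoschedule).

The simulator (`song_schedule()` + `simulate_series()`) generates such
series from a parametric circadian oscillator:

* a singing **window** from `onset_zt` to `offset_zt` (default ZT13 to
  ZT24, matching the observed behaviour of entrained males: onset about an
  hour after lights-off, offset at the end of the dark phase);
* a per-minute Bernoulli probability `p_sing` inside the window (default
  0.8) and `p_noise_sing` outside (default 0.01, sporadic daytime chirps);
* an oscillator **period** `period_h` (tau). Under LD or DL the rhythm is
  entrained: the window is anchored to ZT and the expressed period is the
  24-h Zeitgeber period regardless of tau. Under DD the window is gated by
  the free-running oscillator — singing occurs when
  `(t - onset) mod tau < width` — so the expressed fundamental period is
  exactly tau and consecutive onsets drift by `tau - 24` hours per cycle,
  the classic drifting-onset actogram signature of a free-running rhythm.

Two design points deserve a note. First, the per-cycle (rather than
per-calendar-day) anchoring of the DD window was chosen deliberately: it
makes tau the true generating period, which is the quantity the
periodogram stage is later asked to recover, and it reproduces the drift
law exactly. Second, the nightly activity profile is a boxcar by default
because the window bounds are then identifiable to the minute; a smoothed
raised-cosine `"bump"` profile is also provided since real activity ramps
up and down, but no claim is made about which better matches any real
population — the literature does not quantify the profile shape.

An LD-to-DL reversal (the strongest Zeitgeber perturbation available) is
modelled as a 12-h delaying phase adjustment spread linearly over
`transient_days` (default 4) days. The linear shape is a modelling choice —
transient cycles are real but their shape is not specified by the
behavioural literature we emulate — and the default span matches the
standard practice of discarding the first four post-reversal days as
transients, so analyses never depend on the assumed shape. ZT after the
reversal is referenced to the *new* lights-on.

Between-individual variation in the protocol builders
(`protocol_experiment1/2/3()`) enters as Gaussian jitter of the window
position (SD 1 h) and, under DD, of the free-running period (SD 0.25 h
around a 25.1-h mean). These magnitudes are of the order of the
between-individual spreads reported for entrained and free-running singing
rhythms in this species group; they are fixed once here and not fitted.

## Audio synthesis and what it does (not) emulate

`synthesize_clip()` builds 60-s clips at 44.1 kHz: background noise
(broadband Gaussian at RMS `noise_rms` plus one sinusoidal hum, default
50 Hz, standing in for mains/fan tones) and, for singing clips, one or
more calling-song bouts — a 0.35-s long chirp then six 0.12-s short chirps
at the carrier frequency, 5-ms cosine ramps, embedded at random offsets.
Chirp amplitude is set from `snr_db`, the chirp-to-broadband-noise power
ratio. Clip RMS is linear in the master `amplitude` (verified to 1%), and
no component is driven into clipping at the defaults.

This signal model captures what the detector actually uses — band-limited
energy structure and temporal envelope bursts — but it is deliberately
simple: it has no pulse structure inside chirps, no inter-individual
variation in carrier or tempo, no reverberation, and stationary noise.
Classifier results on synthetic clips therefore demonstrate that the
feature/classifier machinery works at realistic SNR, not that any given
accuracy transfers to field recordings; hand-labeled clips remain
necessary to train a production detector.

## Spectral features

Features are computed from a Welch-averaged magnitude spectrum (Hann
window, 4096-sample frames, 50% overlap — standard bioacoustic practice;
frequency resolution 10.8 Hz) restricted to the 3–6 kHz band around the
song's dominant frequency. The default five-feature catalogue is:

1. **band dominant frequency** (Hz),
2. **band-to-total energy ratio**,
3. **normalized band spectral entropy** (0 = one line, 1 = flat),
4. **band magnitude SD** (the only default feature carrying amplitude),
5. **temporal-envelope crest factor** (peak/RMS of 10-ms block RMS).

A 19-descriptor full catalogue (band magnitude moments, flatness,
centroid/bandwidth/rolloff, envelope statistics, zero-crossing rate,
envelope peak count, broadband RMS, total band power) supports
`pare_features()`, which replays the iterative paring workflow by dropping
the feature with the lowest random-forest permutation importance until
five remain. The default five were chosen by us as the descriptors that
separate the synthetic song from incubator-like noise most directly; the
exact feature list used historically with this kind of data is not public,
so paring is provided as a reproducible procedure rather than a claimed
replication.

Numerical conventions: a silent clip yields entropy and flatness 1 (the
uniform limit) and `NaN` dominant frequency/centroid — flagged, never an
error. One estimator property worth knowing: a pure tone's normalized band
entropy is about 0.15, not 0, because the Hann main lobe spreads a line
over ~3 bins; entropy contrasts (song ~0.2 vs noise ~1.0) are what the
classifier consumes.

## Classifier and evaluation protocol

The detector is a random forest (`ranger`, 500 trees, probability votes;
exact 0.5 votes score as singing, favouring sensitivity) over the feature
vectors, with CART and k-nearest-neighbour learners available for
comparison. Evaluation reproduces the standard protocol: a stratified
75/25 train/validation split, stratified 10-fold cross-validation with the
pooled out-of-fold confusion matrix, accuracy with an exact binomial
(Clopper–Pearson) 95% CI, and Cohen's kappa. Class imbalance is handled by
stratification only.

## Periodogram

`lomb_scargle()` implements the classic normalized Lomb–Scargle
periodogram with the per-frequency time offset that orthogonalises the
sine and cosine terms; power is normalized by the sample variance. It is
evaluated on the unmasked minutes only, which is exactly why LS is the
field's periodogram of choice for behavioural records with gaps. The
period grid spans 18–30 h (covering circadian estimates near 24–25 h with
margin) in 0.02-h steps, and the reported best period refines the grid
maximum by parabolic interpolation through its two neighbours, so
estimates are not quantised to the grid. Tests verify the implementation
against a brute-force per-frequency least-squares fit to 1e-8.

Rhythmicity is tested at `alpha = 0.05` against the closed-form threshold
`z* = -ln(1 - (1 - alpha)^(1/M))`, with `M` defaulting to the number of
natural Fourier frequencies of the observation span that fall in the
scanned period range (a Horne–Baliunas-style estimate). The threshold is
approximate for binary minute data — powers are only asymptotically
exponential — but it is used here exactly as in standard chronobiology
workflows: as a conventional significance line, with all substantive
claims resting on the estimated periods themselves. A constant series
reports zero power everywhere and `is_rhythmic = FALSE` rather than an
error. At least three cycles of the longest candidate period are required.

## Phase markers

Daily onset, peak and offset use the 20%-of-peak rule: per 24-h day the
activity profile is binned (default 30 min) and optionally smoothed with a
centred circular moving average (default 3 bins); the peak is the profile
maximum (adjacent ties resolved to their circular midpoint), the onset is
the **last** upward crossing of 20% of the peak before it (so sporadic
pre-onset chirps cannot drag the onset early), and the offset the first
downward crossing after it, both linearly interpolated between bins.
Days with no activity, or a peak below `min_peak` (default 0.1), return
missing markers rather than fabricated ones.

Bins are timestamped at their left edge, so minute-resolution data
(`bin_min = 1`) are treated as samples at minute starts and the
interpolated crossings of a piecewise-linear profile are exact; at coarser
bins markers carry a timing bias of at most half a bin plus the smoothing
half-window. The binning/smoothing defaults are fixed here and validated
by recovery of simulated windows (to within ±30 min at `p_sing = 0.8`
with 10-min bins), not by concordance with any proprietary tool, whose
internal smoothing is unpublished.

Phases across days or individuals are summarised on the 24-h circle:
circular mean, mean resultant length R-bar, and angular variance
`V_m = 1 - R-bar` (0 = concentrated, 1 = balanced). `phase_shift()`
reports the shortest-arc difference between regime-specific circular
means, signed so a phase advance is positive, with a label-shuffling
permutation p-value (default 10,000 draws). Group equality of periods is
likewise tested by permutation of group labels on the between-group sum of
squares — a deliberately assumption-free alternative to rank tests that
keeps the package self-contained; with five individuals per group the
permutation distribution resolves p-values well below 0.05.

## Trimming and aggregation rules

Analyses mask (never delete) the first 72 h of every series (acclimation)
and the first 4 days after a photoschedule reversal (transient cycles), so
ZT alignment and day indexing survive trimming; equipment gaps are masked
the same way and excluded from every aggregate. Singing effort is total
unmasked singing minutes divided by days contributing data (hours/day).
Dark- and light-phase singing fractions are computed on binary individual
series only, with DD minutes assigned the subjective phases carried from
the prior schedule; the group-averaged fractional series is used for
display (actograms, polar profiles), not for phase fractions, because no
published binarization threshold exists for averaged values.

## Problem sizes and reproducibility

The simulated study conditions used throughout tests and the acceptance
script are those of the emulated designs: 8-day recordings at one-minute
resolution for period work (11,520 minutes per individual), 5 individuals
per temperature group for the temperature-compensation contrast, and
200 60-s clips at 15 dB SNR for classifier evaluation — sizes at which
every property is testable on a laptop. Everything stochastic takes an
explicit integer seed, and identical inputs reproduce outputs exactly,
including the emitted CSV and WAV fixtures.

One statistical caveat is documented rather than hidden: the
temperature-compensation check asks a calibrated 5%-level permutation test
not to reject equality in 10 replicates where the null is true by
construction, so even a perfect implementation fails one replicate with
probability ~0.4 and two or more with probability ~0.09. Observing an
occasional double rejection across seed sets is expected behaviour of a
well-calibrated test, not evidence of a temperature effect.

## Known limitations

* WAV ingestion only (PCM 16-bit); transcoding from field formats is left
  to external tooling, keeping the package bit-reproducible.
* The audio model's simplicity (above) bounds what classifier numbers on
  synthetic clips can claim about real recordings.
* The LS significance threshold is asymptotic for binary data.
* Phase markers at coarse bins inherit a half-bin timing bias; use
  `bin_min = 1` when minute-exact crossings matter.
* Circular regression modelling of phase markers (e.g. projected-normal
  Bayesian models) is out of scope; descriptive circular statistics and
  permutation contrasts are provided instead.
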