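---
title: "Methods: wavelet band features and SVM classification of music-intervention EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet band features and SVM classification of music-intervention EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

`stresswave` implements a complete analysis chain for a common experimental
design in affective neurophysiology: subjects listen to a sequence of short
music interventions while 14 channels of scalp EEG (10–20 montage: C3, C4,
F3, F4, F7, F8, FP1, FP2, P3, P4, T3, T4, T5, T6) are recorded at 256 Hz,
2 minutes per condition (one baseline plus four interventions, MI-1..MI-4),
with self-reported state-trait anxiety (STA, 20–80 scale) before and after.
The analytical questions are (i) which channels and frequency bands carry a
discriminable response to each intervention, separately for male/female and
intervention-vs-baseline contrasts, and (ii) whether the self-reported
anxiety reduction differs between groups.

Because such recordings are rarely shareable, the package includes a
first-class synthetic cohort generator with the same statistical structure,
so every downstream stage is testable and the whole analysis is reproducible
from a seed.

# Pipeline

```
simulate (or ingest EDF/text) -> preprocess -> dwt_band_decompose
  -> extract_features -> wilcoxon_filter -> fit_and_score (per cell)
  -> channel_band_sweep -> make_report / sta_deviation
```

## Synthetic cohorts

Each channel of a simulated recording is a sum of five band-limited carriers
plus background and powerline contamination:

* **Band carriers** — white Gaussian noise band-pass filtered (order-4
  Butterworth, zero-phase) to the conventional band edges used for
  synthesis: delta 0–4, theta 4–8, alpha 8–15, beta 15–32, gamma 32–60 Hz,
  then rescaled to a per-(group, condition, band) RMS amplitude in µV.
  Filtered noise rather than sinusoids is used so that windowed features
  (especially Hjorth mobility/complexity) vary across windows; a pure-tone
  carrier mode exists for spectral oracle tests.
* **1/f background** — white noise spectrally shaped to power ∝ 1/f^α
  (default α = 1, RMS 5 µV), the standard first-order model of resting EEG
  background.
* **Powerline** — a 50-Hz sinusoid (default 2 µV) with per-channel random
  phase, emulating unfiltered mains pickup.

Default amplitudes are 10 µV RMS per band, a realistic scalp magnitude;
contrasts are injected by editing the `[group, condition, band]` amplitude
array (`set_band_amplitude()`). Defaults for cohort structure are the study
conditions themselves: 9 + 9 subjects, five conditions, 120 s per condition,
256 Hz, 14 channels.

Every recording and STA score is a deterministic function of
`(seed, subject, condition, channel)` via a label-hash seed derivation
(`derive_seed()`), so cohorts are bit-reproducible and independent of
generation order.

**STA scores.** The generator draws the pre score uniformly in a per-group
range (male 45–63, female 41–59) and the post score as pre minus a Normal
reduction, clipped to the 20–80 STAI scale. The reported group "deviations"
(7.12 male, 6.38 female) are interpreted as the standard deviation of
*paired pre−post differences* — the quantity `sta_deviation()` computes —
since the source ranges alone cannot identify which marginal they describe;
this choice makes the generator parameter directly recoverable by the
summary statistic. Reduction means are not reported anywhere, so the
defaults (10 male, 5.5 female) are the differences of the midpoints of the
printed pre/post ranges.

What the generator does *not* emulate: eye-blink/EMG artifacts, inter-subject
montage variability, non-stationarity within a segment, the eyes-open/closed
sub-structure of the baseline, or the acoustic content of the interventions
(conditions are labels with configurable band-power effects). Passing tests
therefore demonstrate correctness of the *method* on data with the assumed
structure, not robustness to real-world artifacts.

## Preprocessing

An order-4 Butterworth low-pass at 60 Hz followed by a 50-Hz notch, both
applied forward–backward (zero phase). The filter order is configurable; 4
is standard EEG practice where the source protocol leaves it unstated. The
notch is realized as an order-2 Butterworth band-stop whose stop band spans
`f0/Q` Hz around the notch frequency (default Q = 30, i.e. ≈1.7 Hz wide) —
numerically equivalent in behaviour to the usual IIR notch biquad, and
verified by attenuation tests (>90 % RMS suppression of a 50-Hz tone, <5 %
passband error at 10 Hz).

## Band decomposition

Each channel is decomposed with a 5-level orthogonal discrete wavelet
transform using the Daubechies-7 wavelet, and every coefficient set is
reconstructed to a full-length time series (multiresolution analysis). At
256 Hz the dyadic mapping is

| component | band | edges (Hz) |
|---|---|---|
| A5 | delta | 0–4 |
| D5 | theta | 4–8 |
| D4 | alpha | 8–16 |
| D3 | beta | 16–32 |
| D1+D2 | gamma | 32–64 (nominal) |

Design choices worth making explicit:

* **Dyadic edges.** A dyadic DWT at 256 Hz cannot produce edges like 30 or
  60 Hz exactly; the implementation uses the honest dyadic edges and records
  them in the `band_set`. The "exclusion of 50 Hz" from gamma is handled by
  the notch in preprocessing, not by band splitting.
* **Gamma carries everything above 32 Hz.** The finest detail level D1
  (64–128 Hz) is folded into the gamma series so that the five bands form an
  *exact partition*: delta+theta+alpha+beta+gamma reconstructs the input to
  machine precision for any input. This matches the conventional definition
  of gamma as "≥ 32 Hz"; after the 60-Hz low-pass the content above 64 Hz is
  negligible, so the nominal recorded edges remain 32–64 Hz.
* **Periodic boundary extension.** The transform uses circular (periodized)
  extension, which keeps the filter-bank matrix orthogonal and makes
  reconstruction exact rather than approximate — the additivity property the
  test suite asserts at 1e-8 relative tolerance. Boundary wrap-around
  affects ~14 samples (55 ms) at each end of a 2-minute segment, which is
  negligible at the 30-s window scale. Signals are zero-padded to a multiple
  of 2^5 internally and trimmed after reconstruction.
* The db7 filter pair is the standard orthonormal Daubechies bank (tests
  verify Σh² = 1, Σh = √2, double-shift orthogonality, and energy
  conservation of the transform).

## Features

Every (channel, band) series is cut into non-overlapping 30-s windows
(trailing partial windows discarded; a 120-s segment gives exactly 4
windows) and eight features are computed per window — the 4 × 8 per-cell
feature matrix:

* **Hjorth activity** = var(y) (population variance, µV²);
* **Hjorth mobility** = sd(Δy)/sd(y), with Δ the first difference — for a
  sampled sinusoid of frequency f this is exactly 2·sin(πf/fs), the
  closed form the oracle tests use;
* **Hjorth complexity** = mobility(Δy)/mobility(y), = 1 for a pure sinusoid
  and > 1 for broadband signals;
* mean, standard deviation, variance, skewness, excess kurtosis.

Conventions left open by common usage are fixed as: population moments
(ddof = 0), Fisher (excess) kurtosis, first-difference derivative without fs
scaling (any scaling cancels in complexity; mobility is then a per-sample
angular-frequency proxy). The activity/variance duplication is preserved
deliberately — the feature set is the interface. Zero-variance windows
produce flagged zeros (`degenerate = TRUE`) rather than errors, so silent
channels do not abort a cohort run.

## Feature elimination and classification

Per (subset, intervention, channel, band) cell:

1. **Wilcoxon signed-rank elimination.** The two classes are paired
   row-for-row (ordered by subject rank and window) and each feature's
   paired differences are tested two-sided (exact null for ≤ 25 non-zero
   pairs, normal approximation with continuity correction above; all-zero
   differences give p = 1). Features with p ≥ α (default 0.05) are
   *eliminated*; retained means p < α. The elimination direction is the
   reading under which the filter keeps discriminative features.
2. **Subset assembly.** `male_vs_female` contrasts the two groups'
   intervention windows (positive class male); `baseline_vs_male` /
   `baseline_vs_female` contrast a group's intervention windows (positive)
   against the same group's baseline (negative). With 9 subjects per group
   and 4 windows this is 36 rows per class per cell.
3. **SVM.** Features are standardized with training-set statistics only
   (required for a sane polynomial kernel; can be disabled), then a
   polynomial-kernel SVM (degree 3, coef0 1, C 1, tolerance 0.001 — degree
   and C are the package defaults where the protocol is silent) is fitted on
   a stratified seeded 8:2 split (floor rounding to the training side; a
   2,560-row pool splits 2,048/512) and scored on the held-out part:
   Sen = TP/(TP+FN)·100, Spec = TN/(TN+FP)·100,
   Acc = (TP+TN)/total·100, with empty-denominator metrics reported as
   undefined (`NA`), never 0.

The libsvm backend iterates to tolerance convergence and exposes no hard
iteration cap; `classifier_spec()` records the declared limit (100) as
configuration but cannot enforce it. Cells with fewer than 5 rows per class,
unpairable classes, or no retained features are recorded as *skipped with a
reason* rather than contributing unstable accuracies. Windows are pooled
across subjects before the split (as the pooled sample counts of the design
imply); note this permits subject-level information to appear on both sides
of the split — a caveat inherent to the design, not corrected silently here.

## Reporting

`channel_band_sweep()` covers 3 subsets × 4 interventions × 14 channels ×
5 bands = 840 cells. `make_report()` keeps cells whose accuracy, rounded to
two decimals, is at least the 70 % acceptability threshold; channels sharing
a subset, intervention, band and identical metrics are collapsed into one
display row (presentation only — the full table is always written).
`sta_deviation()` reports per group the pre/post score ranges and the
sample SD (ddof 1) of paired differences. Optional per-region
(central/frontal/parietal/temporal) box plots of the activity feature are
produced when ggplot2 is available.

# Numerical choices and degenerate inputs

* Flat channels: preprocessing and decomposition map zeros to zeros;
  features are flagged degenerate; the Wilcoxon step eliminates all-zero
  differences with p = 1.
* Standardization guards zero-variance training columns (divisor 1).
* EDF I/O quantizes to 16 bits over a padded per-channel physical range;
  round-trip error is bounded by one quantization step.
* Seeds: every stage derives its seed from the global seed and the unit's
  labels modulo a prime below 2³¹, so all seeds are valid R seeds and no
  stage depends on evaluation order.

# Problem sizes used in the checks

The test suite runs reduced cohorts chosen to exercise every code path at
sub-minute cost: parameter-recovery checks use n = 500 subjects per group
for STA (scores only, no EEG synthesis); classification-recovery checks use
the full 9 + 9 × 14-channel × 120-s geometry with the condition list trimmed
to baseline + MI-1; the acceptance computation runs the complete default
cohort (90 recordings, 25,200 feature rows). These sizes are the package's
validation design; the generator's scientific defaults are never reduced.

# Known limitations

* Synthetic validation only: the shipped evidence says the pipeline
  recovers effects of the assumed structure; it cannot certify performance
  on recordings with artifacts or non-stationary backgrounds.
* The pooled-window split can overstate accuracy when subject identity is
  informative; a subject-level split is a natural extension.
* Per-cell test sets are small (16 windows at the default geometry), so
  single-cell accuracies are coarse (multiples of 6.25 %); the sweep reports
  them raw, as the design specifies, and refuses cells below 5 rows per
  class.
* The 840-cell sweep is reported without multiplicity correction, matching
  the source design's reporting convention; treat isolated high-accuracy
  cells accordingly.
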