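# stresswave

Reproducible analysis of music-intervention stress studies from multichannel
EEG and state-trait anxiety (STA) self-reports.

## The problem

A common design in affective neurophysiology records 14 channels of scalp
EEG (10–20 montage) at 256 Hz while subjects hear a baseline period followed
by four 2-minute music interventions (MI-1..MI-4), with STA questionnaires
(20–80 scale) before and after. The analysis asks which channels and
frequency bands discriminate (i) male vs. female responses and (ii)
intervention vs. baseline within each group, and whether the anxiety
reduction differs between groups.

`stresswave` implements the full chain:

1. **Synthetic cohorts** — seeded 14-channel, 256-Hz recordings built from
   band-limited noise carriers with per-(group, condition, band) RMS
   amplitudes, 1/f background and 50-Hz powerline contamination, plus STA
   pre/post score pairs; written/read as EDF or delimited text.
2. **Preprocessing** — zero-phase order-4 Butterworth low-pass at 60 Hz and
   a 50-Hz notch.
3. **Band decomposition** — 5-level orthogonal Daubechies-7 discrete
   wavelet transform; multiresolution reconstruction gives delta (0–4 Hz,
   A5), theta (4–8, D5), alpha (8–16, D4), beta (16–32, D3) and gamma
   (≥32, D1+D2) series that sum back to the input exactly.
4. **Features** — per 30-s window: Hjorth activity `var(y)`, mobility
   `sd(Δy)/sd(y)`, complexity `mobility(Δy)/mobility(y)`, plus mean, SD,
   variance, skewness and excess kurtosis (population moments) — the 4 × 8
   feature matrix per channel/band cell of a 2-minute segment.
5. **Feature elimination** — two-sided Wilcoxon signed-rank test on paired
   class differences; features with p ≥ 0.05 are eliminated.
6. **Classification** — polynomial-kernel SVM (degree 3, tolerance 0.001)
   on a stratified seeded 8:2 split, standardized with training statistics;
   per-cell sensitivity, specificity and accuracy:
   `Sen = TP/(TP+FN)·100`, `Spec = TN/(TN+FP)·100`,
   `Acc = (TP+TN)/(TP+FN+TN+FP)·100`.
7. **Reporting** — the full 3 subsets × 4 interventions × 14 channels × 5
   bands sweep, a filtered table at the 70 % acceptability threshold, the
   per-group STA deviation summary, and optional regional activity plots.

See `vignettes/eeg-music-stress-methods.Rmd` for the model, conventions and
design decisions.

## Worked example

Simulate a 9 + 9 cohort whose male delta-band carrier is four times stronger
(40 vs 10 µV RMS), extract features, and sweep a few channels:

```r
library(stresswave)

cfg <- simulation_config(n_per_group = 9, conditions = c("baseline", "MI-1"),
                         seed = 42)
cfg <- set_band_amplitude(cfg, "delta", 40, group = "male")
cohort <- simulate_cohort(cfg)

features <- extract_cohort_features(cohort$recordings)   # 10080 rows
sweep <- channel_band_sweep(features, subsets = "male_vs_female",
                            interventions = "MI-1",
                            channels = c("C3", "C4", "FP2", "T5"))
rep_ <- make_report(sweep, sta_deviation(cohort$sta))
rep_$filtered[, c("subset", "intervention", "channel", "band",
                  "accuracy", "sensitivity", "specificity")]
#>           subset intervention         channel  band accuracy sensitivity specificity
#> 1 male_vs_female         MI-1 C3, C4, FP2, T5 delta      100         100         100
#> 2 male_vs_female         MI-1 C3, C4, FP2, T5 theta      100         100         100
rep_$sta
#>    group n sta1_min sta1_max sta2_min sta2_max mean_diff  sd_diff
#> 1   male 9 46.93159 60.97449 30.83442 54.71701  9.891857 5.145337
#> 2 female 9 44.51329 57.80772 28.58576 62.38991  8.044247 7.127828
```

The injected delta contrast is recovered at 100 % held-out accuracy in
every swept channel (the leakage into theta reflects the wavelet transition
band — the delta carrier's energy near 4 Hz appears in the adjacent dyadic
band). Cells without a genuine contrast are skipped by the Wilcoxon filter
or sit near chance; at 9 subjects the STA summary is noisy (here the sample
SDs of the 9 paired differences per group happen to order female > male —
the generator's SDs are recovered reliably at larger n, as the tests show).

`run_pipeline(pipeline_config(seed = 1), "out/")` runs the whole chain on
the full default cohort and writes features, sweep tables, STA summary and a
manifest. A thin CLI over the same functions is in
`inst/scripts/stresswave` (subcommands `simulate`, `preprocess`,
`decompose`, `features`, `classify`, `report`, `run`).

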