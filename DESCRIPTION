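Package: stresswave
Title: EEG Music-Intervention Stress Analysis with Wavelet Band Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for studying the effect of music
    interventions on stress from multichannel EEG and state-trait anxiety
    (STA) scores. Generates seeded synthetic 14-channel, 256-Hz EEG cohorts
    with configurable band power, 1/f background and powerline contamination;
    preprocesses recordings (Butterworth low-pass, 50-Hz notch); decomposes
    each channel into the five canonical EEG bands with an orthogonal db7
    discrete wavelet transform; extracts Hjorth (activity, mobility,
    complexity) and moment features on 30-s windows; performs Wilcoxon
    signed-rank feature elimination; and classifies male/female/baseline
    subsets with a polynomial-kernel support vector machine, reporting
    sensitivity, specificity and accuracy per channel and band.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
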