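Package: respyre
Title: Respiratory Rate Estimation from Photoplethysmogram Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating respiratory rate (RR, breaths/min) from
    single-channel photoplethysmogram (PPG) waveforms. Implements the classical
    chain of respiratory-signal extraction (very-low-frequency removal, pulse
    segmentation by incremental line-segment merging, beat-feature series for
    baseline-wander, amplitude- and frequency-modulation, uniform resampling),
    windowed RR estimation (positive-gradient zero crossings, trough-peak breath
    detection, Welch spectral peak), and fusion (smart fusion by agreement of the
    three modulation estimates, spectral peak-conditioned averaging, temporal
    median smoothing); and a compact convolutional + LSTM sequence classifier
    that labels each 30 Hz sample as inhalation or exhalation and derives RR
    from the count of inhalation onsets. A synthetic respiratory-modulated PPG
    generator with ground-truth breath annotations makes every stage testable
    without clinical recordings; readers for the BIDMC and CapnoBase CSV layouts
    handle the public benchmark datasets. Evaluation reports mean absolute
    error, root-mean-square error, percentage error, and the proportion of
    windows within 2 breaths/min (CP2), with automated flagging of
    artifact-corrupted signal windows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
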