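---
title: "Estimating respiratory rate from the photoplethysmogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating respiratory rate from the photoplethysmogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The signal model

A pulse oximeter's photoplethysmogram (PPG) is a pulsatile waveform with one
pulse per heartbeat. Respiration modulates it along three routes:

* **Baseline wander (BW)** — intrathoracic pressure swings add a slow
  oscillation at the breathing frequency to the baseline.
* **Amplitude modulation (AM)** — stroke volume varies over the breathing
  cycle, so pulse heights wax and wane.
* **Frequency modulation (FM)** — respiratory sinus arrhythmia speeds and
  slows the heart, modulating the beat-to-beat interval.

Everything in this package is built around recovering the breathing rate
(RR, breaths/min) from these three imprints, over the physiologically
plausible band of 4–60 breaths/min.

## The synthetic generator

`generate_ppg()` realises exactly this model so that every later stage can be
verified against known ground truth. Each cardiac cycle contributes a pulse
formed by two Gaussians — the systolic peak (centre 0.30 of the cycle, width
0.10 cycle) and a smaller, delayed dicrotic-notch bump (centre 0.62, width
0.12, default height 0.2 of the pulse). A shared respiratory phase oscillator
drives all three modulation routes: the baseline gains
`bw_depth * sin(phase)`, each pulse's amplitude is scaled by
`1 + am_depth * sin(phase)`, and successive inter-beat intervals are scaled by
`1 + fm_depth * sin(phase)`. Breath onsets are defined as the positive-going
zero crossings of the phase oscillator, which makes the ground truth agree by
construction with the zero-crossing estimator's convention. Noise is white
Gaussian; artifacts (spike, step, dropout) are deterministic given their
specification, so the property tests remain analytic and a fixed seed gives
bit-identical output.

The clinical datasets this generator stands in for do not document their
modulation depths; the defaults of 0.1 (10% of pulse amplitude) for all three
routes, with 5% additive noise, are conventional mid-range values for resting
adult recordings and are fixed once here — results in the tests and the
acceptance script are all computed under these conditions. What the generator
deliberately does **not** emulate: realistic arterial pulse morphology and
its beat-to-beat variability, non-stationary breathing, correlated (motion)
noise, and sensor-specific transfer characteristics. Passing the recovery
tests therefore demonstrates the pipeline's correctness, not its clinical
accuracy on intensive-care recordings.

```{r}
library(respyre)
sim <- generate_ppg(synth_config(duration_s = 60, heart_rate = 75,
                                 resp_rate = 15, seed = 1))
autoplot(sim$signal)
```

## Filtering

The extraction chain names only −3 dB cutoffs: a high-pass at 4 breaths/min,
a respiratory band-pass at 4–60 breaths/min, and a PPG low-pass at 35 Hz. We
realise all of them as order-4 Butterworth magnitude responses applied with
zero phase. Rather than running a recursive filter forward and backward, the
squared-magnitude response is applied in the frequency domain on a
mirror-padded FFT: this is the exact steady-state equivalent of
forward–backward filtering, with no start-up transient (a constant input maps
to exactly zero after the high-pass). Because cascading squares the
magnitude, the design cutoffs are pre-warped by
$(\sqrt{2}-1)^{1/(2n)}$ so that the **cascaded** response is −3 dB at the
named frequency; the tests verify the measured gain at the cutoffs to 1%.
Down-sampling (`resample_uniform()`) applies an order-8 anti-alias low-pass
at 45% of the target rate before linear interpolation onto the target grid.

## Pulse segmentation and beat features

`segment_pulses()` follows the incremental line-segment merging idea: the
waveform is split at turning points into monotone segments; oscillations
whose excursion is below 20% of the pulse-amplitude scale (the 95th
percentile of segment excursions) are treated as wiggles — noise ripple or
the dicrotic notch — and merged into the enclosing segment by a single-pass
stack rule. The surviving trough-to-peak rises are accepted as systolic
upstrokes when they reach 50% of the running median (window of 11 beats) of
accepted rise amplitudes, with a refractory rule keeping the larger of two
implausibly close peaks. Beats whose amplitude or interval deviates more than
2.5-fold from the running median are artifact-flagged and excluded from
feature series. None of these thresholds comes from a published
parameterisation; they were chosen conservatively, are exposed as arguments,
and the tests pin their behaviour (clean beat counts exact to ±1; a 10×
spike flagged; beat count stable to 2% under 5% noise).

Beat features are the field's standard ones: pulse amplitude (AM and
"peak amplitude" share the peak-minus-trough definition — the source
material lists both names without distinguishing them), beat-to-beat
interval (FM), peak/trough midline (BW), and consecutive-trough mean. The
irregular series is interpolated to a uniform 4 Hz surrogate (ample for
breathing at or below 1 Hz) by straight lines, an interpolating cubic
spline, or a Berger-style triangular-weighted local average (documented as
approximate), then band-passed to 4–60 breaths/min.

## Windowed estimation and fusion

Three estimators are provided per analysis window: positive-gradient zero
crossings, trough–peak breath detection (a peak counts as a breath when its
rise from the preceding trough exceeds 0.2× the window's interquartile
range, suppressing ripple), and the Welch spectral peak. Welch settings —
segments of at most 32 s, 50% overlap, Hann taper, zero-padding to a grid of
at most 0.5 breaths/min — are our own choices; the method is named in the
source material without parameters. Ties at equal spectral magnitude break
to the lowest frequency, for determinism. A spectral-flatness diagnostic
(geometric over arithmetic mean of in-band power, threshold 0.5) marks
estimates computed from near-flat spectra as low-confidence.

**Smart fusion** combines the BW/AM/FM estimates of one window: if their
standard deviation (sample, n−1 — the usual statistical convention) is below
4 breaths/min the fused RR is their mean; otherwise the window abstains. An
abstention is a first-class outcome (`valid = FALSE`), excluded from metrics
and counted. **Spectral peak-conditioned averaging** normalises each
modulation spectrum to unit in-band power and averages only spectra
concentrating at least 33% of their power within ±0.1 Hz of their own
maximum; the inclusion percentage is never stated in the source material, so
0.33 is a configurable default. **Temporal fusion** is a trailing median of
the most recent three valid estimates — the median is robust to the isolated
gross errors that corrupted windows produce.

## The breath-phase network

The deep route replaces windowed estimation with sequence labelling. The
respiratory surrogate (by default the baseline-wander beat-feature signal,
extracted exactly as in the classical chain) is resampled to 30 Hz, z-scored
per record, and clipped to ±2. The published description of the
normalisation ("rescale between negative two and positive two") does not say
whether values were clipped, winsorised, or merely observed in that range;
we clip, and the fluctuation flagger exploits the rails as an artifact
signature. Per-record (rather than per-window) statistics preserve relative
amplitude differences between windows of one recording.

Labels are self-supervised: a sample above zero is inhalation (1), at or
below zero exhalation (0). The network is one to three stages of 1-D
convolution (same padding), max pooling and ReLU, followed by an LSTM (tanh
cell), a time-distributed dense layer and a softmax over the two classes,
trained with plain SGD on per-timestep cross-entropy. The tuned operating
point is a 210-sample (7 s) window, one conv stage, filter length 1, pool
size 2, batch size 20. Choices the source material leaves open, fixed here:
LSTM hidden size 64; learning rate 0.01; early-stopping patience 10 epochs;
the parameter state at the epoch with minimum validation loss is kept.
Output resolution is the pooled rate (15 Hz at pool 2); pooling truncates a
remainder tail (`floor(T/p)`), so any window length runs with any pool size
rather than erroring on non-divisible combinations. Reference labels are
max-pooled (a pooled step is inhalation if any source sample is), argmax
ties label as exhalation, and a sample exactly at zero is exhalation — both
for determinism. The gradient computation is hand-written and validated in
the test suite against central finite differences to 10⁻⁴ relative error.

RR follows from the labels by counting inhalation onsets (0→1 transitions; a
leading 1 counts). A 7 s window alone quantises RR to ~8.6 breaths/min
steps, so the pipeline evaluates per minute: the predictions of a minute's
consecutive windows are concatenated and onsets are counted over the covered
duration (8 × 7 s = 56 s of each minute). `rr_from_labels()` itself remains
window-agnostic.

Data splits are subject-disjoint by default — the published experiments do
not state whether their 50:50 split separated subjects, and window-level
splitting would leak a subject's breathing pattern from train to test. A
window-level split (`by_subject = FALSE`) is available and is what makes the
split arithmetic exact (e.g. 424 windows at 50:50 → 212 test, 169 train, 43
validation by floor arithmetic).

## Evaluation

`evaluation_report()` reports MAE and RMSE in breaths/min, the mean absolute
percentage error (the per-pair percentage error is signed;
`percentage_error()` exposes it), and CP2 — the percentage of windows within
2 breaths/min, boundary inclusive, following the common usage in the RR
benchmark literature. Windows where fusion abstained are excluded from the
means and counted (`n_abstained`); MAE ≤ RMSE always, and the tests check
the metrics against a naive loop oracle to 10⁻¹².

Corrupted ("fluctuation") segments were removed by visual inspection in the
original workflow; `flag_fluctuation_segments()` automates a stand-in rule:
a window is flagged when its SD exceeds 3× the subject's median window SD or
when more than 10% of its samples sit at the ±2 clip rails. Flags carry
reasons and are never silently dropped; a manually curated exclusion list
can be passed to `evaluation_report()` instead.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` exercise the pipelines at sizes
chosen to make every property measurable on a single CPU in minutes: the
classical chain on 24 eight-minute records (six rates × 32 one-minute
windows), and the deep chain on 200 synthetic one-minute signals
(25 subjects × 8 min, subject-disjoint 50:50 split, 30 training epochs —
validation loss has flattened well before that on this separable task).
Every stochastic component (generation, splits, initialisation, batch order)
derives its stream from one global seed; identical seeds give byte-identical
reports, and each pipeline run can write a manifest recording config, seed
and package version.

## Known limitations

* Synthetic validation only ships with the package: BIDMC and CapnoBase
  readers are provided (CSV layouts), but the published error levels on
  those datasets require downloading them.
* MATLAB containers (CapnoBase's native distribution) and WFDB records are
  not parsed; records must be exported to the documented CSV layouts.
* The filter-based surrogate retains cardiac leakage when the heart rate is
  close to the 1 Hz band edge; the feature-based routes are the reliable
  default (and are what the deep pipeline consumes).
* Berger-style resampling is implemented as a windowed weighted average of
  the event values, an approximation of the original count-rate method.
* The fluctuation flagger is a heuristic stand-in for manual review;
  thresholds are configurable and should be re-examined for new sensors.
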