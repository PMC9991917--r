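---
title: "Methods: models, estimators and design choices in neurowire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in neurowire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

neurowire re-implements, as a tested R pipeline, the analysis methodology of
a wearable platform for human intracranial recording and stimulation:
micro-wire recordings at 38.6 kHz carrying single units and LFP, macro
contacts at 6,250 Hz carrying iEEG and stimulation artifacts, walking and
verbal-memory behavioral sessions, and a closed-loop theta phase-locked
stimulation (PLS) path. No recordings are distributed with the package;
every stage is exercised against synthetic sessions with known ground
truth. This vignette documents the models behind each stage, the tunable
parameters, and the choices we made where the design was genuinely open.

## Synthetic sessions and what they emulate

All generators draw from a seeded RNG and return the exact ground truth
needed to score the downstream stage.

* **Background**: `1/f^a` noise (default exponent 1, the typical LFP
  spectral slope), synthesized by spectral shaping of white noise and
  scaled to a target SD in microvolts. A 60-Hz line component with random
  phase is added with configurable amplitude.
* **Spikes** (`gen_microwire()`): three canonical biphasic 1.5-ms
  templates (sharp negative peak, delayed positive rebound), inserted at
  Poisson times at per-unit rates; amplitude is defined at the waveform's
  absolute peak and ground-truth spike times are logged at that peak.
* **Motion artifacts** (`inject_motion_artifacts()`): slow drifts are
  low-pass-filtered noise confined below `slow_band_hz`; sharp transients
  are 8-ms, 1-kHz bursts under a Gaussian envelope, scaled to a multiple
  of each channel's SD and (by default) identical across channels, as
  cable-borne artifacts are.
* **Theta** (`theta_process()`, used by the walking, memory and PLS
  generators): an amplitude-modulated sinusoid. Burst and gap durations
  are exponential (means 1 s and 1-1.5 s), with raised-cosine on/off
  ramps and a slow frequency wander (SD 0.2 Hz) so the oscillation is
  intermittent and non-stationary, which is the regime the fixed-cycle
  wavelet bandpower analysis assumes. For the PLS input
  (`gen_theta_lfp()`) the default gap mean is 1.5 s (~40% theta
  occupancy), a realistic intermittency that also yields trigger counts
  of the same order as the reference in-vitro run; the ground truth
  carries the full instantaneous oscillator phase series.
* **Walking** (`gen_walk_session()`): repeated crossings with
  crossing_start/end events; during the final third of each crossing the
  theta amplitude of every channel is multiplied by `boundary_gain`
  (1 = null). Each channel has an independent theta process and
  background, so paired per-channel differences are exchangeable under
  the null -- this is what makes the permutation-test calibration test
  meaningful.
* **Verbal memory** (`gen_memory_session()`): blocks of word onsets
  (default 2-s words, 0.8-s ISI, 10 words per block) with Bernoulli
  remembered labels. Remembered onsets receive an additional
  Hann-windowed theta burst over the 2 s after onset with amplitude
  `theta_effect * theta_amp`; `theta_effect = 0` is an exact null (the
  RNG stream is kept aligned so null and effect sessions share the same
  background). This implements an onset-locked theta-power code, the
  feature family the decoder visualization highlights.
* **Stimulation** (`gen_stim_session()`): renders the scheduled biphasic
  pulses on every channel, scaled by per-channel propagation gains plus
  white sensor noise. The default protocol is the full propagation grid:
  amplitudes (0.25, 0.5, 0.75, 1, 1.25) x frequencies (60, 80, 100, 120,
  140) Hz x 4 repeats = 100 bursts of 10 pulses, pulse width 1.28 ms,
  inter-phase gap 150 us, inter-burst 16.67 s.

What the generators do **not** emulate: electrode drift, unit
non-stationarity, correlated multi-unit background, realistic artifact
waveform diversity, behavioral confounds, or volume-conduction structure
across macro contacts. Passing tests therefore demonstrate correctness of
the estimators and calibration of the statistics under the stated model,
not performance on real recordings.

## Filtering and resampling

High/low/band-pass filters are Butterworth designs realized as cascaded
second-order sections; a single `(b, a)` polynomial of order 8 at a 1-Hz
cutoff on a 38.6-kHz recording is numerically unstable, while biquads are
exact (we verified the cascade reproduces `signal::butter`'s frequency
response at moderate cutoffs). A band-pass is a high-pass/low-pass
cascade of the stated order per edge. The 60-Hz notch is a single RBJ
biquad with Q = 30 (~2 Hz wide). Offline stages filter zero-phase
(forward-backward); the PLS simulator uses the causal option. Resampling
is polyphase FIR (`signal::resample`) with the output length pinned to
`round(n * target_fs / fs)`; the paper's chain (38.6 kHz to 386 Hz, and
250 Hz for decoding/concordance) is reproduced by `resample_recording()`.

## Sharp-transient detection

Transients shared across channels are isolated with ICA (in-package
fastICA-style symmetric decorrelation, logcosh contrast, deterministic
whitening and seeded start; 3 components by default). The artifact
component is auto-selected by maximal kurtosis of its 300-3,000-Hz
filtered trace -- sharp transients are far heavier-tailed than spiking
activity -- with a manual override. When the non-artifact subspace is
near-Gaussian its rotation is unidentifiable and the symmetric ICA
iteration cannot meet a tight convergence tolerance; after three seeded
restarts the detector proceeds with the best iterate (warning) as long
as the residual rotation is small, and errors only on unstable fits. Detection thresholds the z-scored
**log-envelope**: the Hilbert envelope of the band-filtered component is
smoothed over 5 ms and log-compressed before z-scoring. The log
transform gives the statistic a light upper tail, so the 4-SD threshold
fires at most about once per minute on artifact-free stationary noise
while 8-SD transients exceed it by a wide margin; thresholding the raw
envelope at 4 SD instead fires tens of times per minute (Rayleigh-tail
false positives) and would make the threshold meaningless. Each
supra-threshold run is padded by 1 ms per side, merged, and removed by
linear interpolation between the samples just outside the interval. ASTR
(artifact-to-signal time ratio) is exactly the removed-sample fraction.
The slow-transient high-pass defaults to the 1-Hz offline cutoff, with
the 4-Hz option covering the full slow-artifact band.

## Spike pipeline

Detection: 300-3,000-Hz zero-phase band-pass, robust noise scale
`median(|x|)/0.6745`, local extrema of `|x|` above `threshold_sd` times
that scale (default 5), 1.5-ms snippets centered on the extremum.
Clustering is deliberately minimal (the reference workflow uses a full
spike sorter): first two principal components, k-means with the cluster
count chosen by mean silhouette width up to `k_max = 5`, falling back to
one cluster below a silhouette of 0.4; seeded and deterministic.
Acceptance requires strictly more than 250 spikes with at most 1% of
ISIs below 3 ms. Firing rates are counts in non-overlapping 50-ms bins
convolved with a unit-area 50-point Gaussian (SD = 50/6 bins, so the
window spans about +/-3 SD; the SD is not stated in the source
description, this is our reading); mass cropped at the series edges is
folded back onto the edge bins so the spike count is conserved exactly.
SNR is `max|mean waveform| / (3 x noise SD)` with the noise SD taken
from the band-passed trace with +/-1.5 ms around each spike excised.
Yield is accepted units per channel. ARI matches before/after sorts
greedily by mean-waveform correlation (> 0.9; ties broken by spike-time
overlap -- no matching rule is stated in the source) and averages the
percent change in per-unit spike counts.

## Spectral estimators

* `cwt_scalogram()`: an analytic generalized Morse wavelet with symmetry
  3 and time-bandwidth 60 (beta = 20), evaluated in the frequency
  domain, 70 log-spaced frequencies from 1 to 125 Hz. The contract is
  peak location and quadratic amplitude scaling, not any particular
  software's coefficient values. Cone-of-influence samples are flagged,
  not trimmed.
* `fft_power()`: transform length = largest power of 2 strictly below
  the series length; coefficients normalized by the transform length
  (documented choice; the alternative reading -- the original length --
  differs only by a constant factor); one-sided power `2|c|^2` without
  doubling DC/Nyquist.
* `welch_psd()`: 8 Hamming segments, 50% overlap, density scaling so the
  integral approximates the variance.
* `bosc_bandpower()`: 6-cycle Morlet power summed over the fixed grid
  (0.25-Hz steps from 3 to 29.75 Hz, 1-Hz steps from 30 to 90 Hz; 169
  points), then z-scored per channel over the full series. Band
  membership is half-open `[low, high)` (the grid top, 90 Hz, closes the
  last band) so adjacent bands add exactly. FFT convolutions are
  zero-padded to a power-of-two length for speed.

## Boundary analysis and the permutation test

Crossings are split at 1/3 and 2/3 of their duration; inner = [A, B),
boundary = [B, end). Condition sizes are equalized by repeatedly
subsampling the larger condition to the smaller one's size (default 500
iterations, seeded) and averaging the subsample means. The paired test
flips the sign of each channel's (boundary - inner) difference; the
two-sided p-value is the fraction of permuted |mean| at least as large
as the observed |mean| (ties count, matching the stated estimator which
can return 0; a `(k+1)/(n+1)` smoothed option exists). The description
of the two-sided test literally counts "larger" differences, which is
one-sided as written; we use the absolute-value convention and keep
one-sided alternatives as options. When `2^n` fits within the
permutation budget the null is enumerated exhaustively, which the test
suite exploits to check the Monte-Carlo path against exact enumeration.
Calibration (type-I error in [0.03, 0.08] at alpha = 0.05 over 200 null
walking sessions) and power (p < 0.01 in >= 95% of boundary-gain-2
sessions) are asserted in the acceptance suite.

## Concordance metrics

Hjorth activity/mobility/complexity use the forward difference scaled by
the sampling rate as the derivative; kurtosis is the population
(non-excess) moment ratio; the artifact spike count is the number of
z-scored samples outside +/-6 after resampling to 250 Hz; 55-65-Hz power
integrates the Hamming periodogram density over the band at 250 Hz (a
unit 60-Hz sine gives 0.5). `concordance_report()` aligns two traces at
250 Hz and reports both trace's metrics plus their Pearson correlation.

## Stimulation engine

Bursts are scheduled as one per (amplitude, frequency, repeat)
combination, `interburst_s` apart; within a burst, pulse onsets are
spaced `1/frequency` (onset-to-onset -- the source sets burst frequency
via the inter-pulse delay without defining reference points, so onset
rate is our convention). Protocol parameters are validated against the
device grid (pulse width 0.01-1.28 ms and inter-phase 0-150 us, both in
10-us steps) and violations name the offending constraint. The grid's
printed amplitude range (0-5,080 in steps of 20, labeled mA) conflicts
with delivered currents of 0.25-1.25 mA, so amplitudes are stored with a
unit label rather than converted. Rendered pulses are charge-balanced
biphasic rectangles (or mirrored 16-step custom shapes). Detection is
normalized cross-correlation against the delivered-pulse template
(threshold 0.8), gated by an amplitude-prominence criterion (window RMS
above 3x the channel's robust noise SD) so the short template cannot
fire on silent channels by chance; detections are assigned to scheduled
pulses, pulse power is the sum of squares over the aligned window
(template span + 2-ms margin; no window is specified in the source), and
every pulse power is normalized by the single largest propagated pulse
across all channels and pulses before the per-condition mean/SD summary.

## Phase-locked stimulation simulation

The simulator is strictly causal. Band power is a sliding 500-ms RMS of
the causally band-passed (3-8 Hz, 4th order per edge) trace, z-scored
against a 10-s running baseline; the trigger gate defaults to 1.5 z.
Phase is tracked from upward zero crossings (sub-sample interpolated) of
the filtered trace; each valid cycle (period within the band) predicts
the next target-phase time from the previous period. Because a causal
band-pass delays the oscillation, the predicted time is advanced by the
filter cascade's phase delay at the detected cycle frequency (computed
from the design, interpolated over the band, and wrapped into the
current cycle so the trigger never uses future samples) -- a real
phase-locking device compensates its known filter delay the same way.
The configured loop latency (default 1.57 ms, the measured round-trip
delay) shifts the landed phase by `2*pi*f*latency`, which the test suite
verifies against the closed form. Triggers respect a refractory period
and never fire during sub-threshold power. Scoring uses the
ground-truth oscillator phase at the stimulation time; the headline
criterion is circular variance (1 - mean resultant length) at most 0.3
on 300 s of SNR-2 synthetic theta LFP, with >= 100 triggers.

## Memory decoder

Windows: 10-s chunks at 250 Hz around each labeled word onset,
multiplied by a Gaussian weight (SD 2.5 s, peak 1 at onset; we weight
the input rather than the loss, matching the description of windows
being weighted), packed per brain-region branch. Recordings at other
rates are 0.1-Hz high-passed and anti-alias resampled first (the
literal "0.1-250 Hz at 250 Hz sampling" band is internally inconsistent
at Nyquist 125 Hz). Classes are balanced by subsampling the majority
class.

Architecture (per branch): conv1 with 32 filters, conv2 with 64 filters,
an LSTM with 64 units, branches concatenated into a 32-unit dense layer
and a sigmoid output; L2 penalty on conv/dense weights; dropout 0.2
after conv and dense layers and 0.1 on the LSTM input; RMSprop at
learning rate 0.001; binary cross-entropy; threshold 0.5. Only filter
counts and the layer types are fixed by the source; kernel geometry and
the head are open. We chose conv1 kernel 50 / stride 25 -- a bank of
learned 200-ms frame features hopping every 100 ms, i.e. a
spectrogram-like frontend -- and conv2 kernel 9 / stride 2, giving a
one-second receptive field (several theta cycles) and a 46-step
recurrent sequence. The engine is in-package (batched BLAS GEMMs over an
im2col layout, BPTT in compiled code, seeded inverted dropout), with
gradients verified against numerical differentiation in the tests.

Two training defaults differ deliberately from the published values,
which were tuned for a ten-participant pooled corpus: recurrent dropout
0.25 instead of 0.5, and minibatch 32 instead of 512. At session scale
(100-200 events) recurrent dropout 0.5 prevents learning altogether (in
our experiments test AUC stayed at 0.5 after 600 epochs, while 0.25
reaches AUC ~0.9), and a 512 batch would collapse training to one
parameter update per epoch. Both published values remain available as
arguments for large-corpus use.

`train_base()` runs stratified k-fold cross-validation (default 5) with
per-fold balancing and a final full fit. `transfer_and_predict()`
freezes the conv and LSTM coefficients exactly (verified bit-identical),
retrains only the dense head after each training block on the
accumulated, shuffled pool of chunks starting from the previous
coefficients (default 20 epochs per block, emulating the fixed
distractor-period budget), then scores the prediction blocks at the 0.5
threshold. Models serialize to a JSON weight manifest (base64 doubles),
and a save/load round-trip reproduces predictions bit-exactly -- the
package's stand-in for the deployment-format conversion step.
`visualize_filters()` performs L2-normalized gradient ascent on an
all-zero 10-s input chunk to maximize a chosen conv2 filter's mean
activation, then maps the optimized chunk through the Morse CWT; filters
with identically zero gradient are flagged dead. `baseline_classifiers()`
provides SVM on decimated raw chunks, PCA+SVM, and a single-hidden-layer
network on the same stratified splits.

## Problem sizes in the test and acceptance suites

The suites are sized for a single desk CPU: calibration uses 200 null
walking sessions (8 channels, ten 6-s crossings at 386 Hz, 2,000
permutations) and 50 gain-2 sessions at 16 channels; the decoder
recovery experiment uses ten seeds per condition with 200-event sessions
(150 train / 50 test, 80 epochs); artifact scoring uses twenty 20-s
4-channel sessions at 8 kHz; the PLS criterion uses one 300-s session.
These sizes are the package's chosen study conditions for its synthetic
experiments; the generators accept larger values.

## Known limitations

* The synthetic data are far cleaner than hospital recordings; absolute
  performance numbers (decoder F1, artifact recall) characterize the
  implementation under the stated model, not clinical data.
* The spike stage is a minimal sorter: no superparamagnetic clustering,
  drift tracking or curation. Any sorter satisfying the acceptance rules
  can be substituted upstream of the quality metrics.
* The wavelet scalogram matches peak locations and scaling laws of the
  reference implementation, not its coefficient values.
* The reported in-vivo headline numbers of the source study (online and
  offline decoding scores, the boundary-theta p-value, per-participant
  yields) depend on patient recordings that are not distributed and are
  out of scope; the package reproduces the self-contained quantities and
  the calibration/recovery properties of the methods.
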