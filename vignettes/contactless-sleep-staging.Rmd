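---
title: "Contactless sleep staging: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless sleep staging: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bcgsleep classifies 30-s sleep epochs from two contactless streams: a
ballistocardiographic (BCG) bed sensor, which reports beat-to-beat (JJ)
intervals and 1 Hz vitals (heart rate, BCG-derived respiration rate BDR,
stroke-volume amplitude), and a bedside microphone. This vignette is the
package's account of the science inside it: the signal model, every
tunable that matters, what the synthetic generator does and does not
emulate, and the numerical choices made where the design was open.

## The signal model

Sleep stages modulate autonomic balance, and autonomic balance modulates
the beat-interval series. Deep non-REM sleep slows the heart and
strengthens respiratory sinus arrhythmia (the high-frequency,
breath-locked oscillation of the beat intervals), while wake and REM
shift power to low-frequency oscillations. The pipeline measures this
along four complementary axes:

1. **HRV features** (per 5-min window, one window per 30-s epoch):
   time-domain (mean JJ, SDNN, RMSSD, pNN50, CV), frequency-domain
   (Welch band powers of the 4 Hz-resampled tachogram; LF 0.04–0.15 Hz,
   HF 0.15–0.40 Hz, their ratio and normalized units), Poincaré geometry
   (SD1/SD2), asymmetry about the line of identity (Porta, Guzik,
   Ehlers' skewness `sum(d^3)/sum(d^2)^{3/2}` on successive differences,
   phase and sector-area indices over above-LOI points), sequential
   trend analysis on successive-difference pairs, sample/approximate
   entropy (m = 2, r = 0.2·SD), detrended fluctuation exponents
   (boxes 4–16 and 16–64 beats) and Rényi entropies of a Gaussian-kernel
   density over 2-beat embeddings (orders 0.25, 2, 5; order 1 is the
   Shannon limit).
2. **Device surrogate**: the bed sensor's own HRV output multiplies the
   HF/LF power ratio by "respiration depth", the mean absolute residual
   of stroke volume about its exponential low-pass
   `y(t) = (1-k) y(t-1) + k x(t)` with k = 0.1 by default. The HF/LF
   orientation follows the device's definition; a switch exposes the
   conventional LF/HF, and another normalizes the residual by the
   smoothed stroke volume.
3. **Cardiopulmonary coupling (CPC)**: both the JJ tachogram and the
   zero-meaned BDR stream are cubic-spline resampled to 2 Hz; a
   1024-sample (512 s) window, slid in 30-s steps and right-aligned to
   each epoch's end, is split into three 512-sample sub-windows at
   offsets 0/256/512, each linearly detrended and Hann-windowed.
   Cross- and auto-spectra are averaged over the sub-windows; coherence
   is `|P_xy|^2 / (P_xx P_yy)` of the averages and the coupling index is
   the per-frequency product `|P_xy|^2 C_xy`, integrated over LF
   (0.01–0.10 Hz) and HF (0.10–0.40 Hz) bands. Sub-window averaging is
   essential: single-segment magnitude-squared coherence is identically
   one. An alternative band-average-then-multiply order sits behind a
   config flag.
4. **Audio features** (per epoch's own 30 s): a 2048-sample/50%-overlap
   Hann spectrogram; the spectral-centroid instantaneous frequency; the
   breathing envelope (per-hop RMS at the frame rate, low-passed at
   2 Hz) whose autocorrelation `r_k = c_k/c_0` yields the respiration
   cycle period (first peak lag, in seconds), intensity (its amplitude)
   and consistency (SD of peak amplitudes); five band energies
   (0–0.1/0.1–0.3/0.3–0.8/0.8–2/2–8 kHz, clipped at Nyquist); SPL
   statistics in dBFS over 100-ms RMS frames; an envelope breath-event
   count; and the low-frequency (< 300 Hz) power share, which rises with
   snoring. An optional spectral-subtraction gate (per-bin noise floor
   from a breath-free profile, over-subtraction 2, gain floor 0.02)
   replaces interactive denoising.

These 43 BCG-side + 19 audio features form the fixed 62-column feature
dictionary (`feature_dictionary()`); one row per epoch, NA wherever a
quantity is undefined — never a silent zero.

## The sequence classifier

`staging_config()` builds the published geometry: two bidirectional LSTM
layers (125 and 100 hidden units, dropout 0.2 after each) feed four
residual blocks of two causal dilated 1-D convolutions (64 filters,
kernel 5, dilation 2^(block-1), per-channel layer normalization with
scale and offset, ReLU, spatial dropout 0.005), with an identity skip
per block and a 1×1 convolution on the skip only in block 1, where
channel counts differ; a 5-class softmax head closes the stack. The
receptive field of K stacked dilated convolutions is
`(f-1)(2^K - 1) + 1`; the formula's K counts convolution layers, and
because dilation here doubles per block (both convolutions of a block
share it, the standard residual-TCN schedule), the idealized bound uses
K = 8 while the built schedule reaches 121 epochs — either convention
can be queried through `receptive_field()`.

Four residual blocks is the unique small block count whose closed-form
parameter sums reproduce all three published head-line counts at once
(TCN-only 169,093; LSTM-only 469,805; combined 690,885), which also
pins down the normalization layer as per-channel scale+offset. The
whole network, including backpropagation through time and the
convolution/normalization adjoints, is implemented in base-R matrix
algebra and verified against finite-difference gradients in the test
suite; no deep-learning framework is involved.

Training (paper-silent, so fixed here): Adam (lr 1e-3), one update per
session-sequence with sessions kept intact and unshuffled,
class-weighted cross-entropy with weights inverse to training stage
frequency (absent classes weight 0 with a warning), global
gradient-norm clipping at 5, at most 40 passes by default with patience
10 on the monitored loss, and a single integer seed controlling
initialization and dropout. Evaluation-mode inference is deterministic.

## Evaluation

Leave-one-subject-out: all sessions of one subject are held out per
fold. Per fold, feature z-scoring uses training-fold statistics only and
residual NAs become 0 after scaling (training-mean imputation), so no
statistic crosses the subject split; the driver asserts the disjointness
of the two sides at run time. Reports cover the 5-class scheme and the
3-class relabeling (`{N1,N2,N3} -> NREM`), with per-fold accuracy and
Cohen's kappa, their cross-fold mean and sample SD (folds are a sample
of subjects), one-vs-rest per-stage sensitivity/specificity/precision/F1
(undefined stages excluded from averaging rather than zero-filled), and
the pooled confusion matrix. Per-stage statistical significance columns
are deliberately not produced: no specific test is part of the protocol
this package implements.

The LOSO driver trains on *all* training sessions and stops on the
training loss. `train_staging_model()` accepts a validation set and
will stop on its loss instead, but at small cohort sizes carving a
validation subject out of the training fold costs more generalization
than the stopping rule recovers (held-out accuracy dropped by 4–8
points in our synthetic-cohort experiments), so the driver does not do
it by default.

## The synthetic generator

No public recordings exist for this kind of paired BCG+audio sleep data,
so `synth_session()`/`make_cohort()` generate the study conditions:

* a first-order Markov hypnogram at 30-s pitch starting in wake, whose
  default transitions make N2 the most frequent sleep stage and put wake
  bouts at the session edges;
* beat intervals
  `JJ = 60000/HR(stage) + A_LF sin(2π·0.09 t + φ1) + g·A_HF sin(2π f_resp t + φ2) + ε`,
  with the LF oscillation fixed at 0.09 Hz (inside the LF band) and the
  HF term at the stage's respiratory frequency, scaled by the stage
  coupling gain g;
* 1 Hz vitals: heart rate, stroke volume amplitude-modulated at the
  respiratory frequency, and a BDR stream carrying a small
  coupling-scaled within-breath oscillation phase-locked to the JJ HF
  term — this is what makes the coupling analysis non-trivial, since a
  perfectly flat rate series would have nothing to cohere with; samples
  are dropped at 1% to emulate network loss;
* audio at 8 kHz (configurable; every default audio feature lives below
  4 kHz): Hann-shaped breath envelopes over a pink-noise carrier, with
  optional 60–270 Hz snore bursts in N2/N3 and a stationary noise
  floor.

Default stage parameters are realistic resting-adult values (HR 56–72
BPM falling with NREM depth, respiration 12–16 breaths/min, HF
amplitude rising and LF falling with depth). The `"separated"` preset
widens these gaps (HR 48–82 BPM, coupling 0.2–2.5) to an idealized
regime used for closed-loop recovery checks. Cohorts add per-subject
jitter (HR ±3 BPM SD, respiration ±0.8, log-normal amplitude scaling)
deterministically per (seed, subject, session).

What the generator does **not** emulate: movement artifacts and arousals,
apneas, ectopic beats, non-stationary ambient noise, microphone
distance changes, stage-transition physiology (parameters switch
instantaneously at epoch boundaries) and real hypnogram architecture
beyond first-order transitions. Passing closed-loop tests therefore
demonstrates that the pipeline recovers the structure it is designed to
measure when that structure is present — not that human-data accuracy
figures transfer.

## Numerical and design choices

* Epoch windows are half-open `[k·30, (k+1)·30)` with 0-based indices;
  per-epoch HRV windows are the 300 s ending at the epoch's end,
  left-truncated (and flagged) for the first nine epochs so every epoch
  owns exactly one feature row; coupling windows reuse the first full
  512-s window for epochs that end before 512 s, also flagged.
* Beat screening: valid JJ ∈ [300, 2000] ms (30–200 BPM) and jumps
  > 30% versus the previous valid beat are masked; masked beats are
  removed, never interpolated, because interval interpolation deflates
  variability metrics. Vitals gaps ≤ 30 s are linearly interpolated and
  flagged; longer gaps stay missing.
* Points exactly on the Poincaré line of identity are excluded from the
  Porta/Guzik denominators (no sign information); a series entirely on
  the line yields flagged-NA indices. Sequential-trend pairs with a zero
  component sit on a quadrant boundary and are excluded from occupancy.
* The Rényi density sums the Gaussian kernel over *all* embedded
  subsequences with an L1 embedded distance; σ defaults to the SD of the
  embedded distances; order 1 routes through the Shannon limit.
* Respiration peak picking: topographic prominence ≥ 0.1, lag window
  1.5–15 s (4–40 breaths/min) and a minimum autocorrelation amplitude of
  0.25 — breathing envelopes concentrate mass at their period while
  white-noise autocorrelations in this lag range stay far below the
  floor, so spurious detections on non-respiratory audio are rare.
* The breath period is reported in seconds (`t1 / F_r`); a switch
  reproduces the literal frame-count×rate product for comparison.
* Coherence on a numerically constant segment is reported as 0 (flagged
  via zero power) instead of a detrend-residual artifact.
* Layer normalization uses ε = 1e-5; LSTM forget-gate biases start
  at 1; weights are Glorot-uniform.

## Problem sizes used by tests and acceptance

Module tests run on short sessions (600–900 s) and small Monte-Carlo
batches. The closed-loop staging check uses a 6-subject, one-session
cohort of 2700 s (90 epochs) each with the `"separated"` preset, the
combined model trained for at most 30 passes — sizes chosen as the
smallest at which recovery is stable. The permuted-label control is the
same cohort with training labels shuffled within sessions: since
non-REM dominates any realistic hypnogram prior (N2 is the most
frequent stage by construction), the raw 3-class accuracy of an
uninformative predictor sits at a prior-driven floor near 50%; "chance"
is therefore judged by Cohen's kappa collapsing to ~0 (observed
agreement equal to chance agreement) and by the prior-robust 5-class
accuracy, not by the raw 3-class accuracy.

## Known limitations

* Human-data accuracy is out of reach by construction (no public data);
  all quantitative claims here concern synthetic recovery.
* The bidirectional recurrent layers break online causality; a
  unidirectional switch would be needed for streaming use, and only the
  TCN-only variant is causal end to end (and is tested for it).
* Pure-R training is practical at cohort scale (minutes), not at
  large-epochs/hyperparameter-search scale.
* The 62-item feature dictionary is this package's fixed reconstruction
  of a feature set whose exact published enumeration is not recoverable;
  the count and the sources are the reproducible contract.
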