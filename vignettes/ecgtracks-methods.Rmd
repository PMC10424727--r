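---
title: "Methods: three-track ECG classification with ecgtracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-track ECG classification with ecgtracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`ecgtracks` classifies cardiovascular conditions from ECG recordings along
three parallel tracks that share one signal loader and one evaluation
harness:

1. **Poincaré track** — R peaks are detected, RR intervals filtered to
   normal-to-normal (NN) intervals, successive pairs (NN~i~, NN~i+1~)
   scattered into a Poincaré diagram, rasterized, and classified with a
   standard 2D image backbone (ResNet50 or DenseNet121) trained from
   scratch.
2. **Raw-signal track** — the signal is first-order differenced,
   standardized, and classified with a 1D convolutional network: either a
   12-block plain CNN or a 1D ResNet with four residual blocks.
3. **Feature track** — a library of time-series features (an "efficient"
   set with the slow families excluded) feeds an XGBoost classifier whose
   hyperparameters are found by Bayesian optimization.

Each track reports macro-averaged F1, sensitivity and specificity, optional
five-fold cross-validation (mean and population SD over folds), a
per-source breakdown with mean signal length, and an efficiency report
(energy, CO~2~-equivalent, and per-record processing/predicting/total
inference time). GradCAM saliency explains the convolutional models; split
frequencies aggregated by feature group explain the boosted model.

No deep-learning framework is assumed: the package carries its own compact
CPU engine (im2col/pooling kernels in C++, backpropagation and Adam in R),
which is what makes architecture audits — block counts, kernel and channel
schedules — directly assertable from a layer-by-layer model description.

# Signal conditioning and beat detection

The bandpass is a linear-phase FIR filter (Hamming window, order
`0.3 * fs` rounded to even) with 3–45 Hz edges, applied forward and
backward (zero phase, output length = input length). The QRS detector
follows the Hamilton design:

* differentiate, rectify, integrate with an 80 ms moving average;
* candidate peaks are integrated-signal maxima that dominate their ±200 ms
  neighborhood (non-maximum suppression);
* an adaptive threshold sits at `noise + 0.45 * (signal − noise)` between
  running means of the last eight signal-peak and noise-peak amplitudes;
* a 200 ms refractory period; a candidate within 360 ms of the previous
  detection whose maximal slope is below half of the previous detection's
  is discarded as a T wave;
* when the gap since the last beat exceeds 1.5× the running RR average, a
  searchback accepts the best skipped candidate above half the threshold;
* only physiologically plausible intervals (0.3–2.0 s) update the running
  RR average, so a stray detection cannot collapse the searchback
  expectation;
* detections are refined to the local filtered-signal maximum within
  ±40 ms.

NN filtering accepts an RR interval when it lies within 0.3–2.0 s and
deviates at most 50% from the running median of the last five accepted
intervals (standard HRV artifact rejection); both bounds are arguments of
`extractNN()`.

# Poincaré images

`rasterizePoints()` maps seconds to pixels linearly over a fixed axis range
of 0.2–1.6 s by default (data-adaptive limits via `axisRange = NULL`).
Fixed limits deliberately leave absolute heart rate visible to the image
classifier: a bradycardia cloud sits at the top-right, a tachycardia cloud
at the bottom-left — without that anchor the image track could not separate
rate-defined rhythms. Each point is a filled disc (radius 2 px) whose
intensity adds in steps of 0.25 and clips at 1, which preserves density
structure inside dense clouds. Reversing an NN series transposes the image
exactly, and that symmetry is property-tested. The single intensity channel
is replicated onto three channels for the standard image backbones.

# Model architectures

**12-block 1D CNN.** Each block is convolution (stride 1, no padding) →
batch normalization (momentum 0.99) → ReLU → max pooling (kernel 2, stride
2) → dropout 0.3. Channels run 256, 256, 128, 128, 128, 64, 64, 64, 64,
32, 32, 32 — the printed endpoints (256 down to 32) with a monotone
interior, which is an interpretive choice. Kernels run 20, then five 5s,
then six 3s. Before the fully connected head there is an average pooling
layer with kernel 1 and stride 2. Max pooling is ceil-mode: with floor-mode
pooling the stack of twelve unpadded convolutions annihilates a
30 s × 300 Hz record before block 12, so ceil mode is what makes the stated
depth consistent with the data it is meant to consume. Inputs shorter than
the minimum receptive length (8,332 differenced samples) are rejected at
build time with the computed minimum.

**1D ResNet.** Stem: convolution kernel 15 to 64 channels, batch
normalization, ReLU, max pooling (kernel 4 — chosen for early temporal
downsampling of long records). Four residual blocks follow with widths 64,
128, 192, 256 — the "increasing from 65 to 256" progression is read as a
channel-width progression, since kernels of size 65–256 would exceed the
feature-map lengths involved; the within-block kernel is 7 with same
padding so the residual addition is shape-consistent, and a 1×1 projection
aligns channels when the width changes. Block layout: conv → BN → ReLU →
dropout → conv → BN, add shortcut, final ReLU. Each block is followed by a
stride-2 max pool (a downsampling choice; the audit surface counts four
residual blocks regardless). The head concatenates global average and
global max pooling — making the network input-length agnostic — and ends in
a fully connected layer sized to the classes.

**2D backbones.** Standard ResNet50 (bottleneck stages 3, 4, 6, 3,
expansion 4) and DenseNet121 (dense blocks 6, 12, 24, 16, growth 32,
bottleneck 4, 0.5-compression transitions), randomly initialized, final
layer sized to the class count. Their batch-norm momentum is 0.9, the
conventional default for these architectures; the 0.99 figure is specific
to the 1D models. A `widthMult` argument scales channel counts (and
`inputSize` the image side) for CPU-sized experiments without altering the
layer structure that the audits check.

## Training loop

Adam (learning rate 10^-3^ by default, β = 0.9/0.999), minibatch size 32,
cross-entropy for multiclass or per-class binary cross-entropy for
multilabel heads (decision threshold 0.5, configurable), early stopping on
validation macro-F1 with patience 5, best-epoch weight restoration. All
stochastic elements (initialization, shuffling, dropout) run under R's RNG
from a single seed, so runs are bit-reproducible.

Batch-norm running statistics are kept as debiased exponential moving
averages (divide by 1 − momentum^n^) and are re-estimated before each
validation pass by a few dropout-free forward passes at the current
weights. At momentum 0.99 and desk-scale step counts, plain running
averages would still reflect activations of long-stale weights, and an
evaluation-mode forward pass through a 12-BN-deep network would be
meaningless; re-estimation is the standard remedy and changes nothing at
convergence.

# The feature track

`extractFeatures()` computes ~140 named features per record
(`group__parameter` naming), covering moments, quantiles, autocorrelation,
FFT coefficient magnitudes and phases, energy ratios by chunks, index mass
quantiles, Lempel–Ziv complexity, range counts, Welch spectral density,
change quantiles, peak counts, threshold crossings, Ricker-wavelet (CWT)
coefficients, C3 and time-reversal asymmetry statistics, linear trend and
CID complexity. Six families are deliberately absent because their cost
dominates extraction time: entropy-type features, matrix profile, CWT peak
counts, partial autocorrelation, aggregated linear trend, and
Dickey–Fuller statistics. Missing values become exactly −999; the variance
filter (threshold 0 — constants only — by default, since "low variance" is
otherwise unquantified) is fitted on training rows only and its retained
column list is persisted and re-applied to held-out data.

Hyperparameters are tuned over: `min_features_to_select` uniform on
[10, #features]; `max_depth` uniform on [2, 100]; `gamma`, `eta`,
`scale_pos_weight`, `reg_lambda`, `reg_alpha` log-uniform on
[10^-3^, 10^3^]. The optimizer is a small in-package Gaussian-process
(RBF kernel) expected-improvement search seeded by a Latin hypercube; the
budget defaults to 100 trials. Each trial performs importance-ranked
feature elimination: a full fit ranks features by split frequency, the top
`min_features_to_select` are kept, and the model is refitted on that
subset. Sampled `eta` values above 1 are capped at 1 inside the booster
call (values up to 10^3^ are in the sampled range but guarantee
divergence); the trial log records the sampled value. Feature importance is
split frequency normalized to sum 1 and summed within the name prefix
before the first `__`.

# Evaluation and efficiency

Metrics are computed one-versus-rest per class — precision TP/(TP+FP),
recall/sensitivity TP/(TP+FN), specificity TN/(FP+TN), F1 the harmonic mean
— and averaged without weights (macro); micro averaging is available via
`micro = TRUE`. With rare classes a zero denominator is possible, so the
convention is explicit: a class that never occurs and is never predicted
scores 1 (nothing to get wrong); any other zero-denominator case scores 0.
Cross-validation folds are stratified by first label (heavy imbalance would
otherwise lose rare classes from folds) and fold summaries use the
population SD (divisor k).

The efficiency harness times the pre-processing and prediction phases
separately per record and reports their averages. Energy is a TDP-share
estimate — assumed CPU package power (65 W default) × elapsed time — and
the report carries an `estimator` flag saying so; no hardware counters are
read. CO~2~ grams are energy × a configurable carbon intensity (0.4 g/Wh
default, a typical grid average). Efficiency numbers are measurements of
the machine they ran on and are never compared against hardware-specific
published values.

# GradCAM

For a target class, the gradient of its pre-softmax logit is taken with
respect to the feature maps of the last convolutional block (configurable),
averaged over positions to weight each map, and the ReLU of the weighted
sum is upsampled (linear in 1D, bilinear in 2D) to input resolution and
max-normalized. The model runs in evaluation mode — dropout off, batch
normalization on fixed statistics — so saliency is deterministic; in that
mode the batch-norm backward pass is the simple linear map through the
stored statistics. The claim that the raw-signal models attend to the
neighborhood of the QRS complex is made assertable through a
planted-pattern control: class identity is carried by a burst inserted in a
known window, and at least half of the saliency mass must fall inside that
window for correctly classified records.

# The synthetic data generator

Each beat is a sum of five Gaussian bumps — P (0.15 mV, σ 25 ms, −160 ms),
Q (−0.10 mV, σ 10 ms, −30 ms), R (1.0 mV, σ 12 ms), S (−0.15 mV, σ 10 ms,
+30 ms), T (0.30 mV, σ 60 ms, +250 ms) — plus a 0.25 Hz baseline sinusoid
(0.1 mV) and white noise (0.05 mV by default). Rhythm classes: sinus
(mean RR 0.8 s with smooth AR(1) variability), AF (i.i.d. truncated-
Gaussian RR with σ = 0.2 × mean and **no P bump** — the irregularly
irregular rhythm and absent atrial activity that define the condition),
tachycardia (mean RR 0.45 s), bradycardia (1.2 s), and a noisy class
(≥0.35 mV noise). Ground truth is the exact R-bump centers. The single-lead
dialect is 300 Hz; the 12-lead dialect draws rates from {257, 500, 1000} Hz
and scales leads by deterministic per-lead factors.

What the generator emulates: rhythm-defining RR statistics, P-wave absence,
realistic amplitudes and rates, two acquisition dialects, label imbalance
on request. What it does not emulate: ectopic-beat morphologies, realistic
12-lead vectorcardiographic geometry, pathologies defined by waveform shape
(bundle branch blocks, ST changes), or non-stationary noise. Passing the
recovery experiments therefore demonstrates that the pipelines learn and
generalize on rhythm-separable data — it does not certify clinical
performance on real recordings.

# Study conditions and problem sizes

The desk-scale experiments the tests and the acceptance script run:

* detector accuracy: 50 mixed-rhythm 30 s records at noise SD ≤ 0.1 mV,
  sensitivity and PPV at 50 ms tolerance;
* 1D ResNet recovery: 1,000 four-class 10 s records at 300 Hz split
  60/20/20, base width 16 (the width multiplier is the scaling knob; the
  architecture is unchanged), ≤30 epochs — with a label-permutation null
  control expected to stay at chance;
* DenseNet121 Poincaré recovery: 1,000 AF-vs-sinus 20 s records, 32 px
  diagrams, width multiplier 0.25, 200 held-out test images;
* boosting recovery: 320 four-class records, 15 of the 100-trial budget;
* GradCAM localization: 200 planted-pattern records, window 501–900 of
  1,500 samples.

One desk-scale limitation is known and deliberate: the 12-block CNN at
reduced width does not reach the 0.90 recovery bar within these budgets —
the plain (non-residual) 12-layer stack with per-block dropout needs far
more optimizer steps than a CPU-scale run provides, and without dropout it
overfits the small synthetic sets. Its tests therefore assert the full
architecture audits, the shape and minimum-length contracts, and that
optimization makes progress (training loss decreases on separable data).
The residual network — which is the point of comparison that motivates
residual connections in the first place — and the image and boosting tracks
all pass their recovery bars at the stated conditions.

# Numerical choices

* 16-bit signal storage at gain 1000 units/mV (round-trip within half a
  quantization step).
* Batch-norm ε = 10^-3^; Adam ε = 10^-8^.
* Ceil-mode max pooling in the 1D CNN (see above); pooling windows at the
  sequence end may be clipped to the available samples.
* Ties in `max.col` decisions are broken by first index.
* Splits: train = round(0.6 n), validation = round(0.2 n), remainder test;
  stratified splitting applies the same rule per class. The default is
  unstratified (a plain random partition of recordings); stratification is
  an option.
* Degenerate inputs: constant leads transform to zeros with a warning;
  records with fewer than two NN intervals yield a blank Poincaré image
  with a warning; fewer than three detected peaks yield an empty NN series.
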