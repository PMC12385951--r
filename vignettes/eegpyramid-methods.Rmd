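---
title: "Residual dilated pyramid networks for EEG seizure classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual dilated pyramid networks for EEG seizure classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Epileptic seizure detection from single-channel EEG is usually framed as
supervised classification of short windows of the raw voltage trace.  The
Bonn corpus is the standard benchmark: five sets of 100 single-channel
recordings (healthy eyes open/closed, interictal from two brain regions,
and ictal), each 4097 samples at 173.61 Hz.  Clinically interesting task
granularities range from binary (healthy vs ictal, e.g. "A-E") through
merged ternary tasks ("AB-CD-E") to the full five-class problem
("A-B-C-D-E").

`eegpyramid` implements a 1-D convolutional architecture for this problem
together with the full surrounding protocol: segmentation, augmentation,
training, stratified cross-validation with t-based confidence intervals,
ablations, and a synthetic data generator that stands in for the corpus so
every part of the pipeline is testable offline.

## Preprocessing

Each record is cut into non-overlapping windows of 512 samples
(`segment_record()`); a 4097-sample record yields 8 windows and the final
sample is dropped.  Coordinates are 0-based and half-open; window `i`
covers samples `[i*512, (i+1)*512)`.

Training folds are augmented by Gaussian perturbation
(`augment_gaussian()`): each training segment S spawns copies

    x = S + alpha * sigma * n,    n ~ N(0, I)

with `alpha = 0.01` and `sigma` the per-segment standard deviation
(population denominator, fixed for reproducibility).  Two copies per
original triple the training set.  Two interpretation points were open and
are pinned here: `sigma` is computed per 512-sample segment (augmentation
happens after segmentation, and the training sample fed to the network is
the segment), and augmentation is applied strictly after the train/test
split, to training folds only, so no perturbed copy of a test record ever
enters training.

## Architecture

The network has four stages (single-channel input of length T, batch B):

1. **Residual convolution module** - two residual blocks.  Each block's
   main path is conv(k = 5, stride 2) - BN - ReLU - conv(k = 5, stride 1,
   dilation 2) - BN; the shortcut is a 1x1 conv (stride 2) + BN; the sum
   passes through ReLU, then dropout 0.3.  Block widths are 64 and 128,
   so the output is (128, T/4).
2. **Dilated convolution pyramid** - five cascaded conv(k = 5, stride 1) -
   BN - ReLU stages at 128 channels with dilations 1, 2, 4, 8, 16 and
   symmetric padding `d*(k-1)/2`, so the length T/4 is preserved.  The
   stack's receptive field follows `RF = 1 + sum((k_i - 1) d_i)` = 125
   samples, which the tests verify against an impulse-probing oracle.
3. **Feature fusion** - for both the shallow (residual) and deep (pyramid)
   feature maps, per-channel global max pooling and per-channel
   differential entropy

       H = 1/2 * log(2 * pi * e * (sigma^2 + eps)),

   with `sigma^2` the unbiased variance over time and `eps = 1e-6`
   (natural logarithms throughout, i.e. nats).  Each of the four
   128-vectors gets its own batch normalization before concatenation in
   the fixed order (pooled-shallow, pooled-deep, entropy-shallow,
   entropy-deep), giving a 512-dimensional representation.
4. **Classifier** - BN - ReLU - dropout 0.5 - linear map to C logits;
   softmax for probabilities.

Conventions pinned so the parameter count is reproducible: convolutions
followed by BN carry no bias; the shortcut includes BN (needed for scale
compatibility before the addition); the final linear layer keeps its bias.
Under these conventions the default five-class model has exactly 568,581
trainable scalars (~569 k), which `count_parameters()` reproduces and the
acceptance script reports.

### Ablation wiring

* `use_rcm = FALSE`: the input is projected to 128 channels by a single
  1x1 convolution (+ BN + ReLU) followed by stride-4 max pooling so the
  pyramid still sees length T/4.  The adapter is the minimal width/length
  match; nothing in the removed module is emulated.
* `use_dcpm = FALSE`: the pyramid is replaced by the identity, i.e. the
  residual output feeds both fusion pathways directly.  This keeps the
  four-way fusion and classifier intact, so the variant removes exactly
  the pyramid's 410,880 parameters — which is also what makes the
  parameter-delta invariant checkable.
* `use_entropy = FALSE`: only the two pooled vectors are fused
  (width 256).

### Entropy variants

For the descriptor sensitivity study the fusion module can swap
differential entropy for Shannon, Renyi, Tsallis (histogram estimators:
16 equal-width bins over each channel's min-max range; orders default
to 2) or spectral entropy (Shannon formula on the DC-excluded normalized
periodogram).  These estimator details are this package's own
reconstructions — the variants are defined only loosely in the
literature — so variant results are a sensitivity analysis, not claims of
equivalence.  The histogram/spectral descriptors are not differentiable;
during training they act as stop-gradient features (gradients flow
through the pooled pathway and the normalization parameters), while
differential entropy is fully differentiated.

## Training

Adam with learning rate 5e-4, weight decay 1e-4, batch size 64, up to 100
epochs, global gradient-norm clipping at 1.0, and label-smoothed
cross-entropy with `alpha = 0.2`:

    y_smooth = (1 - alpha) * y_onehot + alpha / C
    L = -1/N * sum_i sum_j y_smooth[i,j] * log p[i,j]

A probability floor of 1e-12 guards `log(0)`.  With `alpha = 0` the loss
reduces to plain cross-entropy; at uniform predictions it equals `ln C`
for any `alpha`; its infimum is the smoothed-target entropy (Gibbs) — all
three identities are asserted in the tests.

No validation split exists in the protocol: model selection is
"training-set optimum" (highest training accuracy, ties broken by lowest
training loss, then earliest epoch).  Early stopping, whose monitored
quantity was an open point, watches the training loss with patience 10 and
minimum improvement 1e-4; both are configurable.  Data are reshuffled each
epoch with a seed derived from the run seed, so identical seeds give
bitwise-identical histories.

### Numerical implementation

No deep-learning framework is used: the forward pass, backpropagation and
the Adam step are implemented natively in C++ (RcppArmadillo), with
convolutions as im2col + GEMM in single precision.  Gradients of every
layer — including batch normalization and the differential-entropy pooling
(`dH/dx_t = (x_t - mean) / ((sigma^2 + eps) (T - 1))`) — are verified
against central finite differences of the loss via a directional
derivative over the whole parameter vector.

Two numerical choices matter in practice:

* **Precise batch-norm statistics.**  Running moments updated with the
  conventional momentum (0.1) lag the batch statistics when training is
  short, degrading evaluation-mode predictions relative to training-mode
  behavior.  After checkpoint selection, `train_model()` therefore
  performs one deterministic frozen-weight pass over the training data
  and replaces every running mean/variance with the exact aggregate
  moments ("precise BN").  Evaluation then matches converged training
  behavior.
* **Weight initialization** is fan-in-scaled normal, seeded through R's
  RNG, so models are reproducible from `(config, seed)`.

The per-epoch history records the running training accuracy accumulated
over the mini-batch forward passes (the usual convention); it
systematically lags the post-hoc accuracy of the final weights early in
training.

## Evaluation protocol

`run_cv()` performs stratified k-fold cross-validation: per fold, segment,
augment the training portion only, train from a fresh initialization,
select the checkpoint, and evaluate on untouched test segments.  Folds are
stratified at segment level by default, matching the granularity of the
published protocol; `group_by_record = TRUE` switches to leakage-safe
record-level splitting (segments of one record share a fold) — the
published protocol itself notes the absence of subject-independent
validation, and both modes are provided.

Metrics: accuracy, macro-averaged precision/recall/F1, and their
support-weighted counterparts (the weighted F1 is the headline metric for
imbalanced multi-class problems; which averaging the reference tables used
is not stated, so both are emitted).  Per-class ratios with empty
denominators count as 0.  Confidence intervals over fold metrics use the
t-distribution,

    mean +/- t(0.975, k-1) * s / sqrt(k),

with `s` the sample standard deviation; truncation of upper bounds at 100%
is display-only.  Applied to the published five-class fold accuracies this
reproduces the printed mean 95.10 and CI [94.42, 95.78] to two decimals,
which the acceptance tests recompute.

`export_embeddings()` writes per-segment feature vectors (max-pooled
residual or pyramid stages, or the fused 512-vector) with labels, the
input expected by external 2-D projection tools such as t-SNE; the
projection itself is out of scope.

## Synthetic data

`generate_dataset()` emulates the corpus structure (n classes x m records
of 4097 samples at 173.61 Hz) with controllable separability, so training
and evaluation run without any download.  Each class mixes:

* a shared AR(2) baseline (coefficients 1.45, -0.475: poles 0.95 and 0.5,
  giving a 1/f-like spectrum; innovation sd 10 on the microvolt scale);
* a class-specific sinusoid at 4, 10, 16, 24 or 32 Hz, amplitude
  `base_amp * (1 + 0.3 * class_index)` with per-record jitter — easy mode
  uses `base_amp = 25`, jitter sd 1.5 (class band powers separated by
  several within-class standard deviations), hard mode 7 and 5;
* for the last, "ictal-like" class, 3-6 spike-wave bursts of ~1 s at
  random onsets: ~3 Hz alternating-polarity Gaussian bumps with amplitude
  5x the baseline sd (easy; 2x hard).

The design is verifiable without the network: a linear classifier on
closed-form band-power + variance features (`band_power_features()`,
`MASS::lda`) separates easy-mode classes at >90% held-out accuracy, and
each non-ictal class dominates its own frequency band (the ictal bursts
deliberately flood the low bands, which is why that class is instead
distinguished by its broadband variance).

What the generator does **not** emulate: real EEG nonstationarity,
artifacts, inter-subject variability, or the Bonn sets' actual spectra.
Passing tests on synthetic data therefore demonstrate that the pipeline is
correctly implemented and that the architecture can learn separable
oscillatory structure — not that it attains the published accuracies on
real recordings, which would require the corpus itself.

## Problem sizes in the test suite

The packaged checks are scaled to desk hardware as the package's own
choice of test conditions: the end-to-end smoke runs 3-fold
cross-validation on the full-width model over the 500-record easy
synthetic dataset with a 2-epoch budget and augmentation disabled (the
"reduced budget" of the protocol; with precise BN statistics the easy
task saturates within that budget), and compares the full model against
the w/o-pyramid ablation on identical splits across three seeds.  The
training-module smoke uses a reduced-width model (16/32 channels) on 30
records.  All randomness is seeded; reported numbers are recomputed at
run time.

## Known limitations

* Single precision bounds reproducibility across BLAS builds; results are
  bitwise stable on one platform but only near-identical across platforms.
* Histogram/spectral entropy variants are stop-gradient features; if a
  variant were to matter for training dynamics (rather than only for the
  sensitivity comparison), a differentiable relaxation would be needed.
* Multi-channel input is supported as configuration (the first convolution
  accepts any channel count), but no montage construction or resampling is
  provided; corpus-specific preparation pipelines are out of scope.
* FLOP counting and t-SNE are intentionally not implemented (convention-
  dependent and external, respectively).
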