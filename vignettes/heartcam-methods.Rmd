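---
title: "Attention, Grad-CAM and phase-aligned interpretability for heart-sound classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention, Grad-CAM and phase-aligned interpretability for heart-sound classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartcam)
```

## The question the package addresses

A spectrogram-based heart-sound classifier can reach high accuracy while
attending to parts of the signal a cardiologist would consider irrelevant.
`heartcam` packages the full analysis needed to ask, and quantify, whether a
classifier's evidence is aligned with the clinically meaningful parts of the
heartbeat cycle — the first heart sound (S1), systole, the second heart
sound (S2), and diastole — and whether channel attention
(squeeze-and-excitation, SE) or spatial multi-head attention (MHA) changes
that alignment.

The pipeline has three stages:

1. **Preprocessing.** Each single-cycle phonocardiogram (PCG) is denoised
   with a fourth-order low-pass Butterworth IIR filter (600 Hz cutoff) and
   converted to a 224x224 mel-spectrogram image (Hann window of length
   1024, hop 256, 40 mel bands).
2. **Transfer learning.** A frozen convolutional backbone supplies feature
   maps; a trainable head (baseline, SE, or MHA variant) performs 4-way
   classification (normal / systolic murmur / diastolic murmur / combined,
   "abnormal"). Training uses a stratified 70/15/15 split, batch size 5,
   Adam at learning rate 1e-4, and early stopping on validation categorical
   accuracy with patience 10 and best-weight restoration.
3. **Interpretation.** Grad-CAM maps are computed for true-positive test
   samples, converted to predicted activation boxes, and scored against
   phase-derived ground-truth boxes with intersection-over-union (IoU),
   aggregated to per-class and overall mean IoU (mIoU).

## The synthetic data generator

The recordings the original analysis was developed on are not publicly
deposited, so the package ships a generator whose output has the structure
the analysis needs: single heartbeat cycles with exact phase annotations
and murmur timing defining the class.

* S1 and S2 are Gaussian-enveloped sinusoids (defaults about 80 Hz / 90 ms
  and 110 Hz / 70 ms) centred in their intervals — a stand-in for
  valve-closure transients, not a physiological waveform model.
* Murmurs are band-limited Gaussian noise (default 100–400 Hz) with a
  raised-cosine onset/offset over 10% of the interval, confined strictly
  inside the systolic and/or diastolic interval so ground-truth boxes stay
  honest. The murmur level is calibrated so that band power inside the
  murmur interval sits `murmur_snr_db` above the background band power;
  `band_power_db()` verifies the calibration with a Welch estimate.
* Background is white noise at −40 dB relative to unit amplitude; each
  waveform is peak-normalized.
* Cycle duration is drawn from 0.6–1.0 s and divided around physiological
  proportions (S1 10%, systole 30%, S2 8%, diastole 52%) with ±15%
  relative jitter. Sampling rate is 4 kHz (comfortably above twice the
  600 Hz filter cutoff).
* Every cycle's parameters and waveform derive deterministically from the
  dataset seed, the class and the index, so any single cycle can be
  regenerated in isolation.

Two presets reproduce the study designs: `balanced_spec()` (237 cycles per
class, 948 total) and `imbalanced_spec()` (2000/1500/237/1000).

What the generator deliberately does **not** emulate: multi-cycle
recordings, respiration and sensor artifacts, the full disease taxonomy
behind the four timing classes, and — most importantly — the rich spectral
texture of real murmurs. Passing tests on synthetic data therefore show
that the *pipeline arithmetic* is right and that its directional claims can
be probed, not that the classifier would transfer to clinical recordings.

## Preprocessing choices

* The digital Butterworth design places the −3.01 dB point exactly at the
  cutoff; away from the cutoff it approaches the analog magnitude
  `1/(1+(f/fc)^8)` as the sampling rate grows relative to the cutoff. At
  4 kHz sampling the bilinear transform visibly warps the stop band (about
  −34.5 dB rather than −24.1 dB at 1200 Hz); response checks in the test
  suite therefore measure at 44.1 kHz, where the warp is negligible.
* The mel filterbank uses the HTK mel scale with unit-peak triangular
  filters from 0 Hz to Nyquist. STFT frames are centred (zero padding), so
  frame *k* sits at time `k*hop/fs`.
* Powers are converted to dB relative to the per-image maximum and floored
  at −40 dB before min–max normalization to [0, 1]. The floor matches the
  generator's background noise level: a deeper floor (e.g. −80 dB) spends
  most of the image's dynamic range on noise texture below the signal,
  which measurably slows head training and blurs murmur contrast. The
  floor is configurable for data with a different noise level.
* Images with zero dynamic range map to all-zero pixels.
* The mel matrix (40 bands x ~14 frames for a typical cycle) is resized
  bilinearly to 224x224 with low frequencies at the bottom row. Time maps
  to columns by `column = floor(t / duration * 224)` (clamped); this single
  convention is used for ground-truth boxes and any overlay, so box
  geometry is exact by construction rather than inferred from the resize.

## The frozen backbone

No pretrained large CNN weights ship with the package (they are neither
text nor small); the named large architectures raise an informative error
unless the user supplies a feature extractor. All experiments run on
`tiny_test`: a 2x2 average-pool stem followed by three stride-2 3x3
convolution + ReLU blocks (16, 24, 32 channels), giving a 14x14x32 feature
map from a 224x224 input. The stem halves the attention-token count to
196, which keeps the MHA head tractable on one CPU; the random
initialization is seeded and the backbone is strictly frozen — its
parameters receive no updates, and training operates on feature maps
computed once per dataset.

A frozen per-channel standardization (mean/sd computed on the training
split, then fixed) closes the backbone, mirroring the normalization layers
that end real pretrained networks. Without it the random-init features
have a scale around 0.1 and Adam at the mandated learning rate cannot form
a decision function within the early-stopping budget.

## The classifier heads

* **baseline**: global average pooling (GAP), then three dense layers
  (defaults 256/128/64, ReLU) with dropout, then softmax over 4 classes.
* **se**: a squeeze-and-excitation block recalibrates channels first —
  GAP per channel (squeeze), a two-layer gate `sigmoid(W2 relu(W1 z))`
  with reduction ratio r = 16 and bottleneck width at least 4 (excite),
  channel-wise rescaling (reweight) — followed by the baseline tail.
* **mha**: the feature map is reshaped to 196 tokens of dimension 32 and
  passed through 8-head scaled dot-product self-attention
  (`softmax(QK'/sqrt(d_k)) V` per head, concatenated, projected back),
  followed by train-time Gaussian noise (sd 0.1), GAP, and dense layers
  with batch normalization, then softmax.

Defaults the study text fixes are kept (8 heads, key dimension 128,
batch 5, learning rate 1e-4, patience 10, 70/15/15 split). Values the
study leaves open are package choices, configurable and documented here:
dense widths 256/128/64; dropout 0.1 (the head trains on ~100 cached
32-dimensional feature vectors, where the conventional 0.3 is needlessly
aggressive and measurably slows convergence under the fixed learning
rate); value dimension equal to key dimension; Gaussian noise sd 0.1;
maximum 100 epochs. The desk-scale runs in the tests and the acceptance
script use a key dimension of 32 with the 196-token tiny backbone — the
scaled-down problem size, chosen once alongside the other study
conditions.

## Grad-CAM

For class score `y^c` (the pre-softmax logit by default — the standard
choice; post-softmax is available) and last-convolutional feature maps
`A^k`, the channel weights are the spatial means of `dy^c/dA^k`, the
localization map is the ReLU of the weighted channel sum, and the map is
upsampled bilinearly to 224x224 and max-normalized (all-zero maps stay
zero). With the frozen standardization treated as part of the head, the
Grad-CAM target is the backbone's raw convolutional output. Gradients are
exact backpropagation through the head; the test suite verifies them
against central finite differences and a hand-computed toy case.

Predicted activation boxes are extracted by thresholding the map at
`tau * max` (default tau = 0.5), taking 8-connected components, discarding
components below 20 pixels, ranking by total activation mass and keeping
as many boxes as the sample's class has annotated phases. The extraction
rule is a package decision (the published protocol does not specify one),
and tau sensitivity is reported below rather than assumed.

## The interpretability protocol

For each class, 10 true positives are drawn (seeded, uniform; shortfalls
recorded) from the test split. Ground-truth boxes cover the diagnostic
phases: S1 and S2 for normal cycles, the murmur interval(s) for the murmur
classes; they span the full image height by default (the published
examples visibly bound frequency too, but no vertical extent is specified,
so a mel-band restriction is available and off by default). Predicted
boxes are expanded to the ground-truth row span before scoring, so the IoU
measures *temporal* alignment with the cardiac phase — the clinically
meaningful axis — rather than the vertical extent of a saliency blob.
Greedy matching pairs each ground-truth box with the best unused predicted
box (equivalent to optimal matching with at most two boxes a side);
unmatched ground truth scores 0; the sample IoU is the mean over
ground-truth boxes, per-class mIoU the mean over samples, and the overall
score the unweighted mean over classes (class-weighting would conflate the
balancing experiment).

Chance level: each sample's predicted boxes keep their sizes but are
placed uniformly at random 1000 times and re-scored; the mean is the IoU
expected from boxes carrying no temporal information.

## What the synthetic experiments can and cannot show

At desk scale the classifier reaches high accuracy (typically >= 0.95 on
the easy 40-cycle-per-class design at 15 dB murmur SNR), and the full
protocol runs end to end. Grad-CAM localization, however, exposes a real
and instructive limitation: with GAP-based heads on frozen random
features, the class evidence is carried almost entirely by the *extent* of
murmur energy (murmurs cover ~0%, ~30%, ~52% and ~82% of the cycle for the
four classes), because global pooling discards position. For the classes
whose extent lies mid-range (systolic, diastolic), the class score is
locally flat in the murmur channels at the class's own samples — the top
of the evidence hump — so Grad-CAM's gradient weights vanish there and the
maps do not reliably highlight the murmur interval. The end-to-end
above-chance localization check in the acceptance suite documents this
honestly rather than papering over it: on synthetic data with a random
frozen backbone, murmur-class localization hovers at or below the
permutation chance level, while classes with monotone evidence (normal,
abnormal) localize better. Published results with ImageNet-pretrained
backbones sit in a different regime: murmur-selective texture features
make the evidence spatially specific, which is precisely why pretrained
features matter for interpretability and why this package keeps the whole
measurement apparatus in place for users who supply such a backbone.

The attention comparison does replicate directionally at desk scale: over
three seeds on the 24-cycle-per-class design, the MHA head improves both
mean accuracy and overall mIoU relative to the baseline head, driven by
its partial recovery of systolic/diastolic localization. The balancing
comparison does not: the imbalanced arm carries five times as many
training cycles as the scaled balanced arm, and with a random frozen
backbone the extra data improves the head (and its localization) more
than the class skew hurts it. The published balancing effect presumes
feature quality that does not grow with the training set — another
consequence of pretrained backbones that desk-scale random features
cannot emulate. Both comparisons are recomputed, not asserted away, by
`scripts/acceptance.R`.

Tau sensitivity (easy fixture): lowering tau widens blobs and raises both
observed and chance IoU roughly in proportion; the above/below-chance
verdict is stable across tau in 0.3–0.7, which is why tau stays at its
conventional default.

## Numerical and degenerate-input policy

* All randomness flows through `derive_seed()` substreams of one integer
  seed; every reported quantity is reproducible from (data, seed, config).
* Waveforms shorter than one STFT window are centre-padded; empty
  waveforms, out-of-Nyquist bands, unknown class labels, missing phases
  and sampling-rate mismatches raise explicit errors.
* Zero-area boxes have IoU 0 by definition; boxes are clamped, never
  dropped, at image borders; component ties are broken by (x0, y0).
* Batch normalization uses batch statistics in training (eps 1e-5,
  momentum 0.9 running stats) and running statistics in evaluation;
  dropout and Gaussian noise are train-time only.
* Non-finite validation loss aborts training with an explicit error; a
  class absent from an evaluation split yields NA (not 0) F1, flagged.

## Problem sizes used by the tests and the acceptance script

The shipped runs use the easy-separation study (40 cycles/class, murmur
SNR 15 dB) for end-to-end recovery, 24 cycles/class over 3 seeds for the
attention comparison, and the imbalanced design scaled by 10
(200/150/24/100) against a 24-per-class balanced arm for the balancing
comparison. These sizes are the package's chosen desk-scale conditions;
the presets for the full designs are exported and run unchanged, just
longer.
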