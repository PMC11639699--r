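---
title: "Segmenting non-salient lesions: the models and methods behind ntsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting non-salient lesions: the models and methods behind ntsm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Lesions of the oral mucosa photograph almost like the healthy tissue around
them: their mean intensity and texture statistics overlap the background, so
contrast-driven segmentation models under-segment them badly.  The same
"camouflaged target" regime appears in dermoscopy and in natural-image
camouflage detection.  A second, opposite nuisance is that such photographs
also contain *high-contrast structures that are not lesions* — teeth, specular
highlights — which bait any detector tuned to salience.  `ntsm` implements a
convolutional architecture built around two ideas:

1.  **Amplify differences before encoding.**  A *difference-association* (DA)
    module runs on the raw image and explicitly computes local-vs-context
    feature differences (the LCD submodule), then reasons over multiple
    receptive fields to separate true lesions from high-contrast distractors
    (the LSA submodule).
2.  **Replace wide convolutions with grouped Hadamard-product attention.**
    The FHPA block substitutes the second convolution block of the widest
    encoder/decoder stages.  Its parameter count is `~(1 + 1/16) C^2 + O(C)`
    against `9 C^2 + C` for the 3x3 convolution it replaces, which is where
    the architecture's parameter savings come from.

Everything — including the reverse-mode automatic-differentiation engine the
network trains on — lives in this package; compiled convolution kernels are
the only non-R code.

## Module anatomy

### LFE: pooled coordinate gating

`new_lfe(C)` builds the low-level feature extractor.  The input
`(b, C, h, w)` is average-pooled along each spatial axis separately, the two
strips are stacked into a `(b, C, h + w, 1)` tensor (the transposed-stack
arrangement is the only one that lets a shared 1x1 bottleneck see both axes),
mixed through a 1x1 convolution + batch norm + swish at width
`max(C/8, 4)`, split back, and turned by per-axis 1x1 convolutions + sigmoid
into two gates `g_h (b,C,h,1)` and `g_w (b,C,1,w)`.  The output is
`x * g_h * g_w` with broadcasting.  Two exact consequences are frozen in the
tests: zeroed gate convolutions give `0.25 * x` (`sigmoid(0)^2`), and
`|out| <= |x|` elementwise since each gate lies in `(0, 1)`.

### LCE and LCD: normalized local-context differences

`lce_contrast(local, context)` is
`LeakyReLU(InstanceNorm(local - context))` — instance normalization (no
affine, eps `1e-5`, population variance) removes per-plane offsets so only
*spatial structure* of the difference survives.  `new_lcd()` composes two LCE
units: each pairs a local branch (3x3 convolution, dilation 1, then LFE)
against a context branch (3x3 convolution at dilation 4, resp. 8, then LFE).
The two contrast maps are fused by channel concatenation + 1x1 reduction
(configurable to `sum`); concatenation was chosen because it preserves the
two dilation scales as separate channels for the fusion to weigh.

One consequence worth stating plainly: the module is *not* spatially local.
The LFE gates pool entire rows and columns, and instance normalization uses
plane-wide statistics, so perturbing one pixel moves (slightly) every output
pixel.  The locality that does hold — and that the test suite probes — is at
the branch level: before the contrast step, influence is confined to the rows
and columns within the dilated kernel's reach.

### LSA: multi-receptive-field disambiguation

`new_lsa()` takes the LCD output `F_c` through four branches of increasing
depth: (1) 1x1; (2) 1x1 → 7x7 → 3x3 at dilation 7; (3) and (4) 1x1 → 7x7 →
7x7 → 3x3 at dilation 7, with independent weights (they are drawn
identically in topology, *never* tied — a property test takes a gradient step
and asserts they diverge).  Batch norm follows every convolution; GeLU (exact
Gaussian-CDF form) follows all but the last of each branch.  The four outputs
are concatenated (`4C` channels), fused by a dilated 3x3 back to `C`, added
to a 1x1 + BN shortcut of `F_c`, and passed through LeakyReLU.  All
convolutions preserve the channel width `C` because the NTSM formulation
leaves widths unstated; keeping them uniform makes the concatenation width
and the shortcut type-check.

### HPA and FHPA

`new_hpa()` stores a learnable grid `p` (default nominal extent 16x16,
truncated-normal init, std 0.02) plus a depthwise 3x3 convolution.  A forward
call bilinearly resizes `p` to the input's two trailing axes (half-pixel
convention), convolves it, and multiplies the result onto the input — the
gate depends only on `p`, so the operator is exactly linear in `x`.

`fhpa_forward()` group-normalizes, chunks the channels into four equal
groups, and attends each of the first three along a different axis pair:

* group 1: gate over `(h, w)`, one grid slice and one depthwise filter per
  group channel;
* group 2: gate over `(group-channel, h)`; the input is permuted so width
  sits in the batch-like leading position and a single grid/filter is shared
  across it;
* group 3: mirror of group 2 over `(group-channel, w)`.

The single-slice choice for the channel-axis gates is forced by
input-size invariance: a per-width (or per-height) filter bank could not be
learnable while the spatial extent varies between forward calls.  Group 4
takes a pointwise → GeLU → depthwise path, and the re-concatenated groups
pass group norm → depthwise 3x3 → GeLU → pointwise.  No residual connection
is added around the block: the NTSM formulation includes none, and the
substitution site (second conv block of a stage) already sits inside a
skip-connected backbone.

`fhpa_param_count()` gives the closed-form learnable-scalar count; a test
checks it against enumeration of the built block for C in {4, …, 64} and
verifies `count(FHPA) < 9C^2 + C` for every C ≥ 16.

### The assembled network

The backbone is pinned — NTSM is normally mounted on an automatically
self-configured nnU-Net, and an auto-configured topology cannot be
reproduced deterministically, so this package fixes one: stages of two 3x3
conv + BN + LeakyReLU blocks, widths `(32, 64, 128, 256, 512)`, stride-2
strided-convolution downsampling, transposed-convolution upsampling, skip
concatenation.  FHPA replaces the *second* conv block of encoder stages
{3, 4, 5} and decoder stage {1} — the second, because the first performs the
stage's channel change and FHPA is channel-preserving.  The DA module runs on
the raw RGB image (its first convolutions project 3 → 32 channels); its
output is concatenated with the stem features and reduced by a 1x1
convolution.  1x1 heads at the finest three decoder scales emit class logits
for deep supervision.

## Loss

Per supervised scale `i`: `BCE(p_fg, y_i) + k * (1 - softDice(p_fg, y_i))`,
where `p_fg` is the softmax foreground probability, `y_i` the
nearest-neighbour-downsampled mask (top-left convention, preserving
binarity), and `softDice = (2 Σ p y + s) / (Σ p + Σ y + s)` with smoothing
`s = 1e-5`.  Inside training the BCE is evaluated in logit space through a
log-softmax, so its per-pixel gradient is `p - t` and never saturates; the
probability-space form (`bce_dice_level_loss()`, with logarithm clamping at
`1e-7`) is the public per-scale interface and agrees with it away from the
clamp.  Scale weights default to `(1, 0.5, 0.25)` normalized to sum one —
the halving-per-scale deep-supervision convention.  The Dice weight defaults
to `k = 2`: on whole 64x64 images a lesion occupies only a few percent of
pixels, so the pixel-mean BCE is dominated 30:1 by background; at `k = 1`
gradient descent first settles into a confident all-background prediction
and needs several hundred optimizer steps to carve the lesions back out,
while at `k = 2` the Dice term's concentrated foreground pull wins from the
start (the capacity check — four images memorized to Dice > 0.9 — completes
in under 200 of its 300 steps).  Neither `k` nor the scale weights are
prescribed by the NTSM formulation; both are config-exposed.

## Metrics

`ratio_metrics()` computes Sen = TP/(TP+FN), Spe = TN/(TN+FP),
Dice = 2TP/(FP+2TP+FN); a zero denominator yields `NA` ("flagged undefined"),
and dataset means exclude such entries while reporting their count.
`hd95()` treats each mask as the set of its foreground pixel centers
(row-major, 0-based, pixel units), computes both directed nearest-neighbour
distance multisets via an exact Euclidean distance transform, reduces each to
its 95th percentile (type-7 linear interpolation), and combines them by
`max`.  `percentile = 100` recovers the exact Hausdorff distance.  The
percentile variant is the default because that is what "95HD" means in
medical-segmentation evaluation: it discards the extreme 5% of boundary
distances that otherwise let a single stray pixel dominate the metric.

Efficiency indicators: `count_params()` sums learnable scalars;
`estimate_flops()` profiles one inference forward and reports `2 x MACs`
summed over convolutions, bilinear interpolations and Hadamard products (a
hardware-independent count — not a throughput); `checkpoint_bytes()` is the
serialized weight size.  Absolute values depend on the pinned backbone and
are not comparable to numbers obtained on an auto-configured nnU-Net; the
*orderings* (plain > FHPA variants, DA+FHPA < plain) are the meaningful
quantities and are what the tests assert.

## Training protocol

SGD with Nesterov momentum 0.99, initial learning rate 1e-3, weight decay
3e-5, polynomial decay `(1 - t/T)^0.9`, batch size 4, 250 iterations per
epoch and 300 epochs at full scale.  Class imbalance is countered by
forced-foreground sampling: each batch slot independently draws from the
foreground-containing images with probability 0.33 (the sampling reading of
the "lesion-to-background ratio", consistent with an imbalance remedy at the
sampler; a loss-weighting reading would not be).  Validation runs the full
held-out fold once per epoch (replacing fixed 250-iteration validation, which
only makes sense at GPU scale); the best-validation-Dice weights are kept.
The optimizer family is the package's own choice — the protocol names only
the learning rate and weight decay — and is config-exposed.

Batch norm requires `batch_size >= 2` and is enforced in `train_config()`;
at inference the running moments (momentum 0.1, population variance) are
used, making evaluation bit-deterministic.

## The synthetic generator

`generate_sample()` emulates the statistical signature of the clinical
regime, not its anatomy: a background of Gaussian-low-pass-filtered noise
(correlation length `texture_scale`, default 8 px) mapped onto a mid-range
pink palette; lesions as radially perturbed ellipses (three Fourier
harmonics) whose rasterized area is driven into the configured
`lesion_area_frac` bounds, filled with an *independently re-phased* texture
of the same statistics shifted by `contrast_delta` of the dynamic range; and
bright tooth-like distractor blobs placed clear of a 6-px dilation of the
lesions, never entering the mask.  At `contrast_delta = 0` a lesion differs
from its surroundings only in texture phase — the hardest, purely non-salient
case.  Everything is a pure function of `(seed, index)`; PNG output is
byte-reproducible.

What passing tests on this data do and do not show: they demonstrate that the
implementation trains, that its metrics behave, and that segmentation
difficulty scales with the contrast dial; they say nothing about clinical
performance — the generator has no specular highlights, no JPEG artifacts, no
anatomical shape priors, and its lesions are simply connected blobs.

## Numerical choices

* Normalizations use population (biased) variance and eps `1e-5`.
* Bilinear resizing uses the half-pixel (align-corners-false) convention in
  both HPA and the exact adjoint of its backward pass.
* GeLU is the exact `x * pnorm(x)`; swish is `x * sigmoid(x)`; LeakyReLU
  slope is 0.01 everywhere it appears.
* Convolution weights are He-normal initialized (fan-in of the group),
  biases zero; HPA grids truncated-normal (resampled beyond 2 sd).
* All stochastic behaviour flows from explicit seeds: model build, batch
  sampling, and the synthetic generator are separately seeded, so any run is
  reproducible bitwise (training) or to the RNG stream (sampling).
* Mask binarization is `value > 0`; percentile computation is R's type-7.

## Problem sizes used by the tests

The suite trains only desk-scale instances, chosen to exercise every code
path while staying comfortable on a single CPU: stage widths `(8, 16, 32)`,
64x64 images, batches of 4, 300 optimizer steps for the overfitting check
(train Dice > 0.90 on 4 images), 200 steps for the contrast-dial check, and
oracle comparisons on tensors no larger than `(2, 8, 9, 9)`.  The full-width
`(32, ..., 512)` backbone is built for parameter accounting but not trained.

## Known limitations

* 2-D RGB only; no volumetric variant, no multi-class lesions.
* The pinned backbone is *a* faithful nnU-Net-style network, not an
  auto-configured one; absolute parameter/FLOP/Dice values depend on that
  configuration and are not comparable across implementations, so only
  structural orderings are asserted.
* Training in R with a bespoke engine is CPU-bound; the package is a
  reference implementation and experimentation harness, not a production
  trainer.
* Batch norm at batch size 1 is undefined in training mode (the config
  forbids it); instance/group norm paths do not have this restriction.
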