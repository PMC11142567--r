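---
title: "Attention-gated residual U-Net for breast-ultrasound segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-gated residual U-Net for breast-ultrasound segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Breast ultrasound shows tumors as *hypoechoic* (darker) regions embedded in
speckled, low-contrast tissue. Delineating the lesion pixel-by-pixel is the
segmentation task this package addresses: the input is a grayscale image
rescaled to 128 × 128 with values in [0, 1], the output a per-pixel
probability of "tumor", thresholded into a binary mask and scored against a
reference mask with overlap metrics (Dice, IoU) plus accuracy, precision and
recall.

`ultraseg` implements a residual U-Net whose skip connections are gated by a
*positional convolutional block attention module* (PCBAM) and whose
bottleneck carries a projection-based global attention block (SWA), together
with the compound Dice + cross-entropy + focal training objective, a
synthetic phantom generator, dataset utilities and a CLI. Because no
deep-learning runtime is available to R, the forward *and* backward passes
of every layer are implemented in the package itself (base R linear algebra
plus two small compiled kernels); that numerical core is tested against
independent brute-force oracles and central-difference gradients.

## Model

**Backbone.** The encoder has `depth` stages (default 4). Stage *s* is a
residual block at `base_filters * 2^(s-1)` channels: two (3 × 3 convolution
→ batch norm → ReLU) units plus an identity shortcut (1 × 1 projection when
the channel count changes), summed *after* the second activation.
Downsampling between stages is a 2 × 2 stride-2 convolution (+BN+ReLU) that
doubles the channels. The bottleneck is a residual block at
`base_filters * 2^depth` channels. Decoder stages mirror the encoder: a
2 × 2 stride-2 transposed convolution (+BN+ReLU), concatenation with the
attention-gated skip feature, and a residual block. A 1 × 1 convolution and
a sigmoid produce the probability map. The sigmoid is forced by the
objective (the cross-entropy and focal terms take log-probabilities).

Convolutions that feed straight into batch normalization carry no bias
term: under batch statistics BN subtracts the batch mean, so the loss
gradient with respect to such a bias is identically zero and the parameter
could never train. Biases remain wherever no BN follows (attention blocks,
projection shortcuts, output head).

**Channel attention.** The grid is squeezed by global average pooling and
global max pooling into two C-vectors; both pass through a shared
bottleneck MLP (C → C/r → C, ReLU after the first layer, reduction r = 8 by
default) and the sigmoid of the sum gates every channel multiplicatively.
The published description orders the dense layers "C and C/8", which cannot
emit a C-length gate; the implementation uses the standard bottleneck order
and keeps the ratio 8.

**Spatial attention.** The channel-gated grid is pooled *across channels*
into an average map and a max map; each optionally passes through a
per-position dense (1 × 1) layer (`sam_dense`, on by default, with an off
switch because the printed formula is ambiguous about these layers); the two
maps are concatenated and convolved with a 7 × 7 kernel at dilation 4
("same" padding so the gate matches the input), then squashed by a sigmoid —
the published formula omits a squashing function, but its multiplicative use
requires bounded weights. The resulting H × W × 1 gate multiplies all
channels.

**Position attention.** 1 × 1 convolutions produce query/key/value maps
B, Z, D; flattening the plane to N = H·W positions, the affinity
`S[j, i] = softmax_i(B_i · Z_j)` re-expresses position *j* as a weighted sum
of values over all positions, and the output is `alpha * (S D) + F` with the
scalar `alpha` learnable and initialized at exactly 0 — the block starts as
the identity and learns how much global context to mix in. Note the
consequence: at initialization the projection weights receive *zero*
gradient (everything upstream of `alpha` is multiplied by it), so gradient
flow to the projections begins only after the first optimizer update moves
`alpha`; the gradient-flow tests take one Adam step before asserting
coverage. The N × N affinity is never materialized inside the network: a
compiled kernel streams over row chunks in single precision (the working
precision of this computation in GPU frameworks), and the backward pass
recomputes each chunk instead of caching 2 GB of softmax weights. The
exported `position_affinity()` returns the full double-precision matrix for
inspection at moderate grid sizes.

**PCBAM** is the element-wise sum of the position-attention and CBAM
transforms of the same input. With all weights zero both CBAM gates sit at
0.5 and PAM is the identity, so `pcbam(f) = 1.25 f` — a useful algebraic
fixture that the tests assert exactly.

**Bottleneck attention (SWA).** Per-position q/k/v projections (C × C
matrices applied at every pixel), fused by a 1 × 1 convolution of their
channel concatenation (3C → C, the only shape-consistent symmetric reading)
and added residually. The printed equations contain no window partitioning
and no softmax(q kᵀ), and the block is implemented exactly as printed; with
a zero fusion kernel it is the identity regardless of the projections. Its
placement defaults to the bottleneck (the more specific of the two
statements in the source description), with `swa_placement = "decoder"`
applying it after the deepest decoder stage instead.

**Ablation variants.** `attention_mode` ∈ {none, pam, cbam, pcbam} ×
`use_swa` reproduce the five study variants: (i) plain residual U-Net,
(ii) +PAM, (iii) +CBAM, (iv) +PCBAM, (v) +PCBAM+SWA.

## Objective

For mask y and probability map p, with soft counts `tp = Σ y p`,
`fp = Σ (1−y) p`, `fn = Σ y (1−p)`:

* Dice loss `1 − (2 tp + ε) / (2 tp + fp + fn + ε)` with ε = 1e-6 in both
  numerator and denominator, so an empty mask with an empty prediction
  scores 0 rather than 0/0;
* BCE, the per-pixel mean of `−[y log p + (1−y) log(1−p)]`, with p clipped
  to [1e-7, 1 − 1e-7];
* focal loss, the per-pixel mean of `−α (1−p_t)^γ log p_t` with
  `p_t = p` on foreground and `1 − p` on background, α = 0.25, γ = 2 (the
  canonical values; the source never prints them). The published formula
  writes `log(p_i)` with no label branch, which would ignore every
  background pixel; that literal form is available behind
  `loss_config(focal_literal = TRUE)` for comparison.

The training loss is the weighted sum (default weights 1, 1, 1 — the plain
sum); zeroing `component_weights` entries reproduces the single-loss and
pairwise ablations. Dice is computed per image and averaged over the batch
(pooling across images would let large lesions dominate); BCE and focal are
per-pixel means, for which the two orders coincide.

## Training

Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) at learning rate 1e-4 by default,
50 epochs, batch size 8, He-normal initialization keyed to fan-in, all
seeded: weight draws, the train/val/test shuffle (70/10/20 by default) and
per-epoch shuffling derive from `run_config(seed)`, so a rerun reproduces
the identical history and checkpoint. The checkpoint with the best
validation Dice (training Dice when no validation split exists) is kept.

**Batch-norm re-estimation.** At desk scale — a handful of images, tens of
epochs — the exponentially smoothed running moments (momentum 0.9) lag far
behind the batch statistics the network was actually normalized with, badly
enough to destroy inference-mode predictions while train-mode predictions
are excellent. `recalibrate_bn()` therefore replaces the smoothed moments
with the exact population moments over the training set under frozen
weights (momentum-0 passes, pooled across batches); `train_model()` applies
it before every validation scoring and to the final checkpoint. This is the
standard "BN re-estimation" remedy and changes no trainable parameter.

## Synthetic phantoms

Real breast-ultrasound collections cannot ship with a package, so the data
module generates phantoms that emulate the features the model must cope
with, and the generator's defaults define the package's study conditions:

* a smooth low-frequency echogenicity field (sum of four random cosines
  around mean 0.55) for the tissue background;
* one star-convex hypoechoic lesion: a rotated ellipse whose area is drawn
  from 2–25% of the frame and whose boundary radius is perturbed by
  low-order harmonics (amplitude 0.3), with interior intensity reduced by a
  factor 0.35;
* multiplicative unit-mean gamma speckle with variance 0.15 (the standard
  ultrasound speckle model);
* Gaussian point-spread blur, σ = 1.5 px, applied to the image only;
* quantization to 8-bit levels, so writing PNGs and reloading them is
  lossless.

The mask is the exact pre-blur lesion indicator, and each phantom is a pure
function of `(seed, index)`. What the phantoms deliberately do **not**
reproduce: acoustic shadowing and posterior enhancement, multiple or
non-star-convex lesions, probe-dependent anisotropy, annotation noise, and
the benign/malignant appearance difference. Passing tests on phantoms
therefore demonstrate that the architecture, objective and training loop
work end-to-end — not clinical-grade performance on real ultrasound, for
which users should point `load_image_mask_dir()` at a BUSI-layout dataset
(`<root>/<class>/<name>.png` + `<name>_mask*.png`, multiple mask files
unioned, the tumor-free "normal" class excluded unless requested).

## Numerical choices and degenerate inputs

* Softmax rows are shifted by a maximum before exponentiation; the affinity
  kernel shifts by the chunk maximum and falls back to exact per-row maxima
  when the logit spread could underflow a row.
* Thresholding uses `p >= threshold` (ties go to foreground), threshold 0.5
  by default — the source reports hard metrics without printing either.
* Zero-denominator metrics: if ground truth and prediction are both empty,
  overlap ratios score 1; if exactly one is empty, 0.
* Mask resizing is nearest-neighbor with re-binarization at 0.5; images are
  resized bilinearly; color PNGs are converted by luminance.
* Batch norm uses biased batch variance, momentum 0.9, eps 1e-5.
* `split_dataset` floors each fraction and assigns the remainder to the
  training set (n = 10 → 7/1/2); k-fold test folds differ in size by at
  most one and partition the data exactly.

## Problem sizes used by the tests and the acceptance script

The suite verifies the attention algebra against O(N²C) loop oracles on
grids up to 4 × 4 × 4 (100 random draws), network gradients against central
differences, and the full five-variant forward/backward at 128 × 128
(depth 3, base 16, channel-MLP reduction 4 so every hidden layer keeps ≥ 4
units — dead-at-init ReLU units are a property of random draws, not of the
architecture the check targets). The training-convergence check and the
acceptance script use a depth-3, base-8 model with CBAM + SWA gating:
full-resolution *training* with position attention costs O(N²) per image
per step (N = 16384), which is out of reach of a single-CPU run, while the
PAM/PCBAM training path is exercised at 32 × 32 and their full-resolution
forward/backward in the variant matrix. The overfit run uses 8 phantoms,
learning rate 1e-3 and stops once training Dice reaches 0.93; the
generalization run trains on a 70/10/20 split of 24 phantoms for up to 45
epochs and reports held-out test metrics.

## Known limitations

* Training at full resolution with position attention on the first skip is
  computationally heavy on CPU (the affinity is quadratic in pixel count);
  the architecture supports it, wall-clock does not at desk scale.
* The SWA block follows its printed equations — projection fusion with a
  residual — and therefore contains no actual windowed softmax attention;
  no experimental substitute is provided.
* Batch-norm statistics assume batches of more than one image for stable
  training; `batch_size = 1` degenerates to per-image normalization.
* The checkpoint format is R serialization (RDS) with an embedded config
  and version field; it is not interoperable with other frameworks.
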