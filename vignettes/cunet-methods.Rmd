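---
title: "Methods: boundary-aware nucleus segmentation with cross-scale fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boundary-aware nucleus segmentation with cross-scale fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model, the preprocessing and evaluation
procedures, the synthetic data the package tests itself on, and the
numerical and design choices a maintainer needs to know. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The segmentation model

The task is binary nucleus segmentation of RGB cytology images, with
instances recovered afterwards by 8-connected component labeling. The
network is a UNet-style encoder followed by gated cross-scale fusion and
two coupled decoders.

**Encoder.** Seven resolution levels ("seven levels" is read as seven
resolutions, i.e. six 2×2/stride-2 max-poolings). Each level applies two
3×3 same-padding convolutions with ReLU. Channels double per level from
`base_channels` (default 64) up to `channel_cap` (default 512), giving
64, 128, 256, 512, 512, 512, 512. The cap keeps the deep levels tractable
(uncapped doubling to level 7 would require 4096 channels) and follows
standard feature-pyramid practice. Dropout
(default rate 0.5) is applied at the deepest level only, and inside the
gating units.

**Gating and lateral projections.** Levels `levels_used` (default 3–7)
are projected by 1×1 convolutions to `fpn_channels` (default 64) and
passed through a gating unit `x ⊙ dropout(σ(BN(conv₁ₓ₁(x))))` that
suppresses low-relevance regions. A five-level bidirectional pyramid over
p3–p7 is the standard configuration for this fusion style: the finest two
levels are expensive and noisy at full width, while p3–p7 still spans a
16-fold scale range. The level-6 output additionally feeds the wide
context unit.

**Weighted fusion.** Every fusion node combines equal-shape inputs as
`Σ ReLU(vᵢ)xᵢ / (Σ ReLU(vⱼ) + e)` with per-node learnable scalars
initialized to 1 and `e = 10⁻⁴` — fast normalized fusion: the rectifier
keeps every effective weight non-negative and `e` stabilizes the
normalization. Normalized weights are non-negative and sum to strictly
less than 1.

**CSFI stack.** `n_layers` (default 3) bidirectional passes. Top-down:
`pᵒₗ = ConvBNReLU(fuse(pᵢₙₗ, R_b(pᵒₗ₊₁)))` where `R_b` is bilinear
resizing to level-l resolution; the deepest level passes through. Bottom-up:
`pᵒᵘᵗₗ = ConvBNReLU(fuse(pᵢₙₗ, pᵒₗ, R_b(pᵒᵘᵗₗ₋₁)))`. At the range ends the
missing neighbour is dropped: the shallowest node fuses `(pᵢₙ, pᵒ)` and the
deepest fuses `(pᵢₙ, R_b(pᵒᵘᵗ))` — including `pᵒ ≡ pᵢₙ` there would count
the same tensor twice. All convs in the stack are plain 3×3 + BN + ReLU; they are
bias-free because a bias feeding BatchNorm is mathematically dead (BN
subtracts the channel mean), which also lets the gradient-coverage test
require a nonzero gradient for *every* parameter.

**Wide context unit.** Two parallel compositions of orthogonal 1-D
convolutions — `conv₁ₓN(convNₓ₁(x))` plus `convNₓ₁(conv₁ₓN(x))` — with
N = 7 by default, balancing context against rim effects at the 1/32 scale
where the unit operates. Each
branch has an N×N effective receptive field; the test suite verifies
equality with a dense composed-kernel oracle. The WCU consumes the CSFI
output at level 6; the deepest decoder node fuses the level-7 CSFI output
with the bilinearly-resized WCU feature.

**Interconnected decoders.** Top-down over the used levels. Segmentation:
`Pˢₗ = ConvBNReLU(fuse(pₗ, R_b(Pˢₗ₊₁), R_b(pₗ₊₁)))`. Boundary:
`Pᵇₗ = ConvBNReLU(fuse(Pˢₗ, R_b(Pᵇₗ₊₁), R_b(pₗ₊₁)))` — the boundary branch
consumes segmentation features, never the reverse, which the ablation test
verifies (zeroing all boundary parameters leaves the segmentation output
bit-identical). Each head ends with a 3×3 then 1×1 refinement unit,
bilinear upsampling to the input size, a 1×1 convolution and a sigmoid:
with a single foreground class a 1-channel sigmoid head is the natural
choice (a 2-class softmax would be equivalent in effect).

**Spatial-constancy caveat.** All-convolutional translation equivariance
makes the output constant for constant input only where no contributing
feature map is pure padding rim. With 7 levels on small inputs the deepest
maps (1–2 px) are all rim, and their variation spreads through bilinear
upsampling; the constancy tests therefore use a 4-level configuration at
256 px where every contributing level keeps a padding-free interior and
the property holds to machine precision.

## Losses

With `p` the predicted probabilities and `t` the binary target, sums over
pixels within an image and means over the batch:

- Dice: `1 − (2Σpt + E)/(Σp + Σt + E)`, `E = 10⁻³`.
- BCE: `−(1/P)Σ[t log p + (1−t)log(1−p)]`, predictions clipped to
  `[10⁻⁷, 1−10⁻⁷]`.
- Focal Tversky: `TI = (TP + E)/(TP + α·FP + β·FN + E)`,
  `loss = (1 − TI)^(1/γ)` with defaults α = 0.3, β = 0.7, γ = 4/3 — the
  common recall-weighted setting for small-structure segmentation. With
  α = β = 0.5, γ = 1 the loss reduces to Dice — exactly so when the
  smoothness constant is halved on the Tversky side, since E meets a
  half-weighted denominator there; the tests assert the exact form. A
  floor of 10⁻¹² under `1 − TI` keeps the focal exponent's gradient finite
  at perfect predictions.
- Combo: `α·CE_w − (1−α)·DSC` with class-weighted cross-entropy
  (foreground weight β) and defaults α = β = 0.5; bounded below by
  `−(1−α)`, which is asserted.
- Heads: segmentation `FT + w_seg(Dice + BCE)`, boundary
  `FT + w_bou·Combo`, with `w_seg = w_bou = 0.4`; total =
  seg + `head_balance`·boundary (default 1.0, the neutral equal
  weighting).

Per-image sums with batch-mean reduction keep the composite weights
comparable across crop sizes. Every loss is built once as a differentiable
graph; the exported numeric functions evaluate the same graph, so training
and the public API cannot drift apart.

## Training runtime

SGD with momentum 0.9 and weight decay 5e-4; learning rate 0.001 and batch
size 10 by default. Random square crops (default 256 px) and optional
augmentation per sample per epoch; validation Dice each epoch; the best
checkpoint is kept; early stopping after `early_stop_patience` epochs
without improvement (patience 0 stops after the first epoch). Checkpoints
are self-describing (parameters, BN statistics, all configuration blocks,
seed) and reloading reproduces validation Dice exactly.

**Precise-BN re-estimation.** BatchNorm running statistics use decay 0.99
during training. Over short runs this EMA lags the moving activation
distribution badly, and the statistics are also geometry-dependent: crops
and full padded images have different channel statistics (white padding
shifts means). Before each validation pass the running statistics are
therefore replaced by the exact average of batch statistics over up to 8
full padded training images at fixed weights — matching the inference
geometry. This is the standard precise-BN technique; the training-time EMA
decay remains 0.99.

Prediction pads inputs with white to the required divisibility (2^(levels−1)),
records the offsets in a sidecar JSON, and un-pads the outputs — inputs
are never silently cropped.

## Preprocessing

**Stain separation.** OD = −log((I₂₅₅+1)/255) per channel; pixels with OD
norm below `od_floor` (default 0.15) are background. Stained pixels are
factorized OD ≈ C·B (C ≥ 0 the per-pixel densities, B ≥ 0 the 2×3 basis
with unit rows) by alternating closed-form two-stain NNLS coding with a
multiplicative basis update and per-iteration row normalization, 200
iterations, initialized from the published H&E reference vectors; no
randomness is used, so fits are exactly repeatable. The L1 sparsity weight
(default 0.1) applies to the density-map coding that sets the robust
per-stain maxima (99th percentiles), *not* to the basis alternation:
hematoxylin and eosin OD vectors are only ~37° apart, and an L1 penalty
coupled into the basis fit collapses mixed nucleus pixels onto single-stain
supports, rotating the hematoxylin vector by roughly 10° toward the nucleus
mixture color almost independently of the penalty size — which the package's
own recovery tests (5° tolerance against the known rendering basis) reject.
Rows are ordered hematoxylin-first by the red-minus-blue OD component
(hematoxylin transmits blue). Normalization rescales source densities by
the ratio of target to source maxima and recombines with the target basis;
zero-density (white) pixels stay white.

**Boundary enclosing.** Operates on ground-truth masks at dataset
preparation time, before augmentation. For each foreground component
touching the border, its border contacts are clustered along the image
perimeter cycle; the gaps between clusters are closed along the *shortest*
border arcs (the largest arc is left open), and the enclosed region is
filled. Filled components with a contiguous border run are untouched, so
the operation is idempotent; interior components are never modified.

**Boundary targets.** Per-instance morphological gradient (dilation minus
erosion, disc of radius ⌈thickness/2⌉, default thickness 2 px): processing
instances separately guarantees that pixels between touching instances are
boundary. Thin 1-px targets destabilize the boundary loss on downsampled
crops, hence the 2-px default.

**Augmentation.** Geometric transforms (horizontal/vertical flips,
resize-rescale, integer translation, elastic deformation) act identically
on the image (bilinear) and both targets (nearest-neighbor, preserving
binarity); photometric transforms (Gaussian blur, two noise models,
hue/saturation/contrast) act on the image only. Everything is a pure
function of (inputs, policy, seed). Elastic fields whose gradient would
fold the sampling grid are rescaled with a warning. Count preservation:
flips and translation of interior objects are exact; rescaling is not a
rigid transform and preserves count only up to nearest-neighbor
row-duplication quantization — about 5% at nucleus radius ~10 px, the
stated interpolation tolerance (a half-pixel bias in the NN index map was
fixed: the nearest source pixel of sample point p is ⌈p⌉, because pixel
centers sit at half-integers).

## Evaluation

Pixel metrics from exact confusion counts; ratios with empty denominators
are `NA`, never silent zeros. F1 is `2PR/(P+R)`. For binary masks F1 equals the Dice coefficient,
asserted to 1e-12. Two empty masks have Dice 1 by convention (with a
message). An F1 definition without the factor 2 would cap at 0.5 and break
the F1–Dice identity, so the standard form is used.

Object metrics are built on one-to-one instance matching: pairwise DSC
over overlapping (gt, pred) pairs, greedy in descending DSC above the
threshold (default 0.7), ties broken by ascending ids for determinism.
At threshold 0.7 the matching is provably optimal: DSC > 0.7 implies
IoU > 0.538 > 0.5, so no instance can exceed the threshold with two
disjoint partners and the candidate graph is already a matching. At
permissive thresholds greedy is a maximal matching (within one of the
optimal assignment on small toys; the tests document this). Definitions:
`recall_o = matched/n_gt`, `fnr_o = 1 − recall_o`,
`acc_o = matched/(n_gt + n_pred − matched)` (union-normalized,
Jaccard-style; pred-normalization is the one-flag alternative).
Connected components for instance recovery use 8-connectivity, implemented
in C++ with deterministic scan-order labels.

## Synthetic cytology scenes

The generator emulates the statistical structure of liquid-based cytology
fields: elliptical nuclei (default 5–60 per 1024×768 field, major semi-axis
10–26 px matching ~8–16 µm nuclei at ~0.32 µm/px), moderate eccentricity,
a bounded fraction of overlapping pairs with deterministic z-order
(later-placed on top; the semantic mask is the union), optional border
truncation, eosin-tinted cytoplasm halos (2.2× the nucleus ellipse),
unannotated impurity blobs, Beer–Lambert RGB rendering through a known
stain basis, Gaussian blur and additive noise. Beer–Lambert rendering makes
the stain-separation round trip exactly testable: the generator's basis is
the recovery oracle. Scenes are pure functions of (params, seed).

What the generator does **not** emulate: chromatin texture, out-of-focus
planes, folded cell clusters, mucus and inflammation, scanner-specific
color response curves, or megapixel fields. Passing tests therefore show
the pipeline is *correct* (shapes, gradients, metrics, determinism, and
that the model can fit cytology-like signal); they do not certify clinical
performance on real Pap smears.

Study conditions for the convergence smoke property were fixed up front:
four 64×64 scenes with 2–3 large nuclei (semi-axis 14–22 px), mild blur and
noise; reduced model (base 8 channels, cap 64, fpn 16, dropout 0); SGD with
learning rate 0.05 and momentum 0.9. The learning rate differs from the
full-scale default because that value is tied to the full model and batch
size; a reduced 400k-parameter model tolerates and needs a larger step.
The acceptance script uses twelve 96×96 scenes with 3–5 nuclei, overlap and
border truncation enabled, an 8/2/2 split, and at most 150 epochs with
patience 30 — sizes chosen so the whole pipeline runs in minutes on one CPU
while every stage (stain fit, training, prediction, object metrics) is
genuinely exercised.

## Numerical machinery

The network runs on a compact reverse-mode autodiff tape: each operation
records its parents and a backward closure; C++ kernels (im2col + GEMM
convolution, 2×2 max-pool with argmax routing, half-pixel-center bilinear
resize with exact adjoint) carry the heavy arrays. Gradients of every
primitive and of the composed loss graphs are verified against central
finite differences; the bilinear backward is verified as the exact adjoint
(⟨R x, y⟩ = ⟨x, Rᵀ y⟩). Eval-mode forwards drop parent links so
intermediates are garbage-collected, and are bit-deterministic across
calls; training is bit-reproducible under a fixed seed on one device
(single-device contract; multi-device synchronous BN is out of scope).

## Known limitations

- CPU-only: full-width training at realistic crop sizes is slow; the
  package is sized for method verification, not large-scale training.
- The boundary head shares the segmentation head's supervision framework
  but no boundary-distance metrics (Hausdorff/ASSD) are provided.
- Stain separation assumes exactly two stains and Beer–Lambert attenuation;
  Pap-stain polychromes with more dyes are outside the model.
- `acc_o` union-vs-pred normalization is an interpretation (see above).
- Early stopping monitors validation Dice only; patience defaults to 15
  epochs.
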