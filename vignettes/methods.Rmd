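---
title: "Methods: anatomically constrained vector-quantized state-space segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anatomically constrained vector-quantized state-space segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

`hepaseg` implements joint liver and tumor segmentation for 3D
contrast-enhanced CT. The model is a 3D U-Net whose encoder levels are
multi-scale context blocks, with two modules inserted at the bottleneck — a
learnable vector-quantization codebook followed by a selective state-space
(linear recurrence) sequence module — and a hybrid objective

L = L_seg + alpha * L_VQ + beta * L_contain

with defaults alpha = 0.4, beta = 0.6.

**Multi-scale context block.** Three parallel branches: (1) a 1x1x1
reduction followed by a 3x3x3 convolution (receptive field 3), (2) a 1x1x1
reduction followed by a 3x3x3 convolution with dilation 2 (receptive field
5 — the dilation rate is chosen exactly so a k=3 kernel spans 5 voxels per
axis), and (3) global average pooling followed by a 1x1x1 convolution and a
spatial broadcast. Branch outputs are concatenated along channels and fused
by a 1x1x1 convolution. Each convolution is followed by instance
normalization and ReLU; instance norm is chosen because the training
protocol uses batch size 1, where batch norm statistics are degenerate.
Branch 3 skips normalization (a single pooled site has zero variance).
A test-only `linear` mode disables all normalizations/activations so the
block's linearity and receptive fields can be asserted by impulse
responses.

**Codebook.** Bottleneck feature vectors z_n (one C-vector per spatial
site) are assigned to the nearest of K learnable prototypes by squared
Euclidean distance (ties to the lowest index, a deterministic rule that
makes assignment exactly testable). Defaults K = 64, C = 64. The forward
pass uses the quantized features; the straight-through estimator passes the
downstream gradient to the encoder unchanged. The VQ loss is the two-term
form — both terms share the value ||Zq - Z||^2 and differ only in which
side is treated as constant: the commitment term (weight 1) updates the
encoder, the codebook-update term (weight lambda = 0.25) updates the
prototypes. Two deliberate choices:

* **Mean reduction** over sites and channels. The reference formulation
  writes an unreduced squared norm; a mean keeps lambda and the hybrid-loss
  weights comparable across input sizes.
* **Gradient-based codebook updates** (no EMA), matching the printed
  two-term loss. Prototypes are initialized uniform(-1/K, 1/K).

A note on terminology: the source material labels the unweighted term
"commitment" while elsewhere calling lambda the commitment weight; the loss
is implemented exactly as the printed two-term expression, with lambda on
the codebook-update (encoder-detached) term.

**State-space module.** The bottleneck volume is flattened depth-major
(axial position varies slowest, so each slice is a contiguous block) and
run through the gated linear recurrence

h_t = a_t * h_{t-1} + W_b x_t, y_t = C_out h_t,
a_t = exp(-softplus(W_a x_t + b_a)) in (0,1)^n.

Design rationale, where the reference formulation leaves freedom:

* The input-dependent transition is realized as a **diagonal contractive
  gate**: every entry of a_t lies in (0,1), which guarantees numerical
  stability (the recurrence is a contraction; a sup-norm bound is asserted
  in the tests) and admits an unrolled closed form used as the test oracle.
* The input injection B(x_t) x_t is a **single linear map** W_b x_t: a
  generated matrix composed with x_t is itself linear in x_t at first
  order, so one matrix suffices at equal expressive order.
* **Unidirectional scan** with h_0 = 0 by default; a bidirectional flag
  exists but is off (the default keeps the module identical to its causal
  description, and causality is a tested invariant).
* A **residual connection** wraps the module so zero parameters give the
  identity; no discretization machinery (no dt-rank, no depthwise
  convolution), since only the recurrence itself is specified. As a
  consequence the module's parameter count is not comparable to published
  profiling figures, which is documented rather than imitated.
* Bottleneck order is codebook first, then the state-space module, per the
  reference ablation's statement that the sequence module consumes the
  codebook output.

**Network assembly.** Four encoder levels (widths 16/32/48/64) with max
pooling (2,2,2) at the first three levels and (1,2,2) at the fourth: a
48-slice slab keeps depth 6 at the bottleneck. A depth-1 bottleneck (as
implied by one published profiling table) is reachable through
configuration, but the pooling schedule that produces it is unstated, so it
is not the default. The decoder mirrors the encoder with
transposed convolutions whose kernel equals the pooling factor; skip
connections are center-aligned (crop when larger, zero-pad when smaller,
off-by-one to the trailing side). Two **sigmoid heads** emit liver-region
(labels 1 and 2) and tumor probabilities. Head biases are initialized at
approximate class-prior log-odds (liver-region ~25%, tumor ~1% of voxels) —
the standard remedy for extreme foreground/background imbalance: with
zero-mean initialization each head starts near probability 0.5 over the
whole volume, and early training is dominated by false-positive cleanup
rather than learning the structures. This is the central
interpretation choice: the containment loss compares T(x) against L(x) and
is only meaningful when the liver map covers the whole organ including
tumor tissue; a mutually exclusive softmax would penalize every true tumor
voxel. Whether published liver scores treat the organ as labels 1+2 or
label 1 only is unstated, so the metrics expose both reductions.

**Losses.** The segmentation loss is not prescribed by the reference; the
de-facto standard (soft Dice with eps = 1 smoothing + binary cross-entropy,
averaged per head and across the two heads) is used, keeping its scale
commensurate with weights near 0.5. The containment loss is the mean over
all voxels (literal reading of its 1/N; restricting N to liver-adjacent
voxels would change only the scale) of max(0, T(x) - L(x)), computed on
soft probabilities so it is differentiable.

## Preprocessing

The chain follows the stated order literally: clip to (-200, 200) HU,
resample (cubic B-spline for images — a true prefiltered B-spline with
mirror boundaries, solved exactly via the tridiagonal system — and
nearest-neighbour for masks) with in-plane factor 0.5 and axial spacing
normalized to 1 mm, randomly sample a liver-containing 48-slice axial slab,
then min-max normalize. Two decisions where the statement is silent:

* The slab start is drawn **uniformly among all windows containing at least
  one liver voxel** ("randomly sampled" is otherwise unspecified).
* Min-max normalization is **per slab** (the slab is the tensor actually
  fed to the network). Whether the original normalization was per volume or
  per slab is unknown; this is flagged, not guessed as intent.
* Volumes shorter than the slab are zero-padded symmetrically (extra slice
  trailing) and the padding is recorded.

Resampling is center-aligned (output voxel i samples input coordinate
(i + 0.5) * in/out - 0.5), preserving the physical field of view.

## Synthetic phantoms: what they emulate and what they do not

The generator emulates the data regime of LiTS-style abdominal CT:
anisotropic voxels (default 1.5 mm axial, 0.8 mm in-plane), one large
smooth organ (an axis-aligned ellipsoid, default semi-axes 25/30/28 mm,
mean 100 HU, emulating a contrast-enhanced liver), hypodense interior
lesions (spheres, 4-12 mm radius, mean 40 HU), soft-tissue background
(-20 HU), additive Gaussian noise (sd 10 HU), and optionally one lesion
placed fully outside the organ to exercise the containment prior. Lesions
carve out of the liver label (mutually exclusive 0/1/2 codes, the LiTS
convention); the whole-organ region downstream is codes 1 and 2.

Shapes are deliberately analytic — an ellipsoid and spheres have
closed-form volumes, so voxelization can be checked against lattice-point
oracles. One RNG stream (the config seed) governs placement and noise, so
equal configs are bit-identical. The phantoms do **not** contain realistic
CT texture, vasculature, contrast phases, neighbouring organs, or
respiratory deformation. A green phantom test therefore establishes the
*mechanics* of the pipeline (shapes, gradients, losses, metrics,
determinism, the containment effect) — it says nothing about clinical
segmentation accuracy, and the published LiTS-scale scores are explicitly
out of desk-scale reach.

Intensity means/noise were chosen once as plausible contrast-enhanced CT
values (portal-venous liver ~100 HU, hypodense lesions ~40 HU, noise
sd 10 HU) and are not tuned against any test.

## Training protocol

Adam with lr 1e-4, beta1 0.9, beta2 0.999, eps 1e-8, weight decay 1e-5
(added to the gradient, the PyTorch convention), batch size 1, 160 epochs,
constant learning rate (only the initial rate is specified). Replicate
seeds (42, 57, 89); reports are mean +/- sample sd (n-1). Validation split
and checkpoint selection are this package's own choices (best mean
liver+tumor Dice when a validation set is given, final state otherwise),
since the reference states only that a random split was used.

## Metrics: numerical conventions

* **VOE = 1 - Dice.** The printed Jaccard-style formula evaluates to -1
  for identical masks, while every published (Dice, VOE) pair sums to
  exactly 1; the operational definition is therefore 1 - Dice, with the
  strict Jaccard variant behind a flag.
* **RVD** uses the printed |P| denominator; |G|-denominator and absolute
  variants are flags (published positive "RVD down" tables suggest an
  absolute value was reported).
* **Surfaces** are 6-connectivity boundary voxels; distances come from an
  anisotropic squared Euclidean distance transform (lower-envelope method)
  in mm. The 95th percentile uses linear interpolation between order
  statistics (R type 7, numpy "linear").
* **Empty predictions**: Dice 0, distances undefined-with-flag, RVD
  undefined when its denominator mask is empty; both-empty Dice is 1 with
  a flag.
* **Size strata** use the maximum axis-aligned voxel extent of each
  26-connected ground-truth component (a true 3D Feret diameter is the
  plausible alternative; the axis-aligned reading is implemented and
  flagged), with half-open bins <10, [10,20), [20,30), [30,50), >=50.
  Per-component Dice is computed in the component's bounding box padded by
  5 voxels, ignoring voxels of other components inside the box.

## Numerical implementation notes

The network is implemented with hand-written backward passes; 3D
convolutions run through compiled im2col + GEMM kernels in single
precision for CPU throughput (inputs, parameters and all other paths stay
double). All oracle-equality tests (codebook, state-space scan, metrics,
losses) go through pure double-precision code. Distance-transform scan
lines without features use a large finite sentinel rather than infinity.
Quantization distances clamp tiny negative values (cancellation) to zero.
Auto-padding makes any input size divisible by the cumulative pooling
factors and crops the outputs back; it is never silent truncation.

## Known limitations

* Batch size is fixed at 1 (matching the training protocol); there is no
  multi-volume batching, no GPU path, and no sliding-window inference.
* The published parameter/FLOPs/latency figures and the LiTS benchmark
  tables are out of scope by design; ablation switches reproduce the
  architecture axis, not the published numbers.
* NIfTI support covers single-frame 3D volumes with the common scalar
  datatypes, slope/intercept scaling and diagonal orientation — not the
  full NIfTI feature set.
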