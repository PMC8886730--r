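---
title: "A single-body, multi-scale-heads attention mechanism for radiograph classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A single-body, multi-scale-heads attention mechanism for radiograph classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Most self-attention modules for convolutional classifiers (squeeze-excite
gates, pooling-based spatial attention) are lightweight blocks inserted
independently at several depths: each block sees only its own feature map,
so there is no global attentional context shared between scales. This
package implements the opposite design: one *single* high-capacity
attention body — a U-Net-style encoder-decoder `G(·)` reading the input
image `x` directly — whose output is shared by *multiple scale-specific
heads* feeding the backbone at every stage.

The encoder-decoder produces a raw map `A_G` with the input's spatial
dimensions. Everything downstream consumes its bounded form `σ(A_G)`,
where `σ` is an elementwise logistic. For backbone stage `j` with feature
map `F_j` of shape `(h_j, w_j, c_j)`, the scale-specific head computes

```
A'_j  = B_j(σ(A_G))          bilinear resize to (h_j, w_j)
Ā_j   = C_j(A'_j)            one convolution, c_j output channels
F̄_j   = Ā_j ⊗ F_j + F_j      residual multiplicative gating
```

and `F̄_j` feeds the next stage. The `⊗` is elementwise; the `+ F_j`
residual means a zero attention map is exactly the identity, a property
the test suite asserts bit-exactly.

Two readings of the published formulation were genuinely open and were
decided as follows:

* The per-scale block `C_j` is described as a single convolution with
  "filter size c_j", but the equation lists `F_j` as an argument. No
  mixing operation is ever described, so `C_j` here convolves the resized
  prior alone and `F_j` contributes only its target shape. The kernel's
  spatial extent is likewise unspecified; shape algebra only forces `c_j`
  output channels, so the kernel defaults to 1×1 (channel adaptation) and
  is configurable to 3×3.
* The logistic is applied *before* bilinear interpolation, the order the
  architecture diagram states. Since interpolation is convex, the resized
  prior stays strictly inside (0, 1).

One bilinear convention — half-pixel centers, clamped
(`src = (i + 0.5) · n_in / n_out − 0.5`) — is fixed package-wide and used
both for image loading and for the attention priors; the tests check it
against an independently coded direct evaluation of the interpolation
formula.

`σ(A_G)` is computed once per forward pass and shared by all heads; this
weight- and computation-sharing is the point of the "single body"
design, and it is also what lets the map double as a human-readable
explanation (the heat-map overlays of `global_heatmap_overlay()`).

## The encoder-decoder

The published description names a U-Net and nothing else, so depth,
widths and normalization are configuration choices here: depth 4 with
channel doubling from 16 base channels by default, skip connections on,
and nearest-neighbour-plus-convolution upsampling rather than transposed
convolutions (transposed kernels produce checkerboard artifacts, which
are particularly unwelcome in attention maps that double as explanation
devices). The raw, pre-logistic map is the module boundary so that
segmentation pretraining and the attention heads share one bounded map.
There are no normalization layers; initialization is He-normal.

The per-scale projections are **zero-initialized**, so every gate starts
as the exact identity and the full model's forward pass initially equals
the bare backbone's. This matters for the training dynamics: with
randomly initialized heads, classification gradients reaching a freshly
pretrained encoder-decoder through large random projection weights
destroy the pretrained attention map within a few epochs at desk scale.
Zero-initialized gating (the same device as zero-γ batch-norm in residual
networks) lets the heads grow into the pretrained global map instead of
trampling it.

## Training procedure

Two devices, mirroring the published recipe:

**Segmentation pretraining (transfer learning).** The encoder-decoder is
first trained so that `σ(A_G)` matches binary lung masks, with an equally
weighted binary cross-entropy + soft-Dice loss. The resulting weights
initialize (and keep training in) the full model, steering global
attention toward the lung fields from the start.

**Alternating freeze/train.** Training alternates between the two
components: during a *main* epoch only backbone and classifier-head
parameters update; during an *attention* epoch only encoder-decoder and
per-scale-projection parameters do. The published description says one
block is frozen "during each step" without defining the step; per-epoch
alternation is the coarsest consistent reading and the period is
configurable. Freezing is enforced by excluding the frozen side from the
optimizer, and the tests verify bit-identical frozen parameters across
epochs. The per-scale projections are assigned to the attention side
(they are described as part of the attention block); a configuration
switch moves them to the main side. The best-validation-accuracy
checkpoint is retained (earliest epoch at a strict improvement).

During attention epochs the encoder-decoder steps with a reduced
learning rate (factor 0.1 by default) relative to the projection heads —
ordinary discriminative fine-tuning of a pretrained component. Besides
stability, this breaks a real symmetry of the residual gate: a head with
negative weights over a globally *inverted* attention map discriminates
exactly as well as a positive head over the lung-focused map, and with a
uniform rate small-sample training sometimes drifts into the inverted
solution, discarding what pretraining established. Anchoring the
pretrained map makes the classification loss itself prefer positive
heads on lung-focused attention.

Default hyperparameters follow the published recipe: Adam, learning rate
8e-5, batch size 16, 480×480 inputs, no preprocessing beyond resizing.
The classification loss is 2-class cross-entropy (the publication never
states a loss; its three benchmark tasks are all binary).

## Synthetic phantoms: what they emulate and what they do not

The package bundles a deterministic phantom generator so every module is
testable without external image cohorts. A phantom is two elliptical
"lung fields" (darker, as radiolucent regions) on a brighter body
background with bounded uniform pixel noise. Positive phantoms add 2–4
truncated Gaussian opacity blobs *inside* the lungs; both classes add
1–3 identical blobs *outside* the lungs, emulating the wires, text
burn-ins and acquisition artifacts that real public CXR collections
carry. Because the off-lung distractors are class-independent, the
discriminative signal is lung-confined by construction — which is exactly
the situation in which a lung-focused global attention map is useful, and
what makes the attention-focus test below meaningful rather than
vacuous. Distortion modes (crop/pad, inversion, burned text, letterbox)
reproduce the qualitative anomaly types at the generator level.

Specific numeric choices, made once:

* Noise is uniform with configurable standard deviation (default 0.02
  intensity units). Bounded support makes negative phantoms separable
  from positives *by construction*: no lesion-free lung pixel can exceed
  the lung background mean by more than √3 ≈ 1.73 standard deviations,
  while lesion contrast is required to exceed 3 standard deviations.
* Lesion contrast defaults to 0.4 with radii between 1/16 and 1/8 of the
  image side — clearly visible opacities, appropriate for the small
  sample sizes and model capacities of desk-scale runs.
* Masks are written as 0/255 PNGs and thresholded at 128 on read;
  lossless and inspectable.
* Train/val/test splits (70/15/15) are assigned by a deterministic
  FNV-1a hash of sample index and seed, so a manifest is reproducible
  without a stored split file.

What phantoms do *not* emulate: anatomy (ribs, mediastinum, clavicles),
realistic opacity texture, patient positioning, scanner characteristics,
label noise. Passing phantom tests therefore demonstrates that the
mechanism, the training contracts and the pipeline work as specified —
not that the model reaches any particular accuracy on real radiographs.

## Desk-scale study conditions

The heavier tests and the acceptance script run one fixed configuration,
chosen once as a realistic miniature of the full recipe:

* 64×64 phantoms; encoder-decoder depth 3 with 8 base channels; a
  3-stage convolutional backbone (8/16/32 channels) with one attention
  head per stage; ~64k parameters in total.
* Adam with learning rate 5e-4 and batch size 32 for the classification
  stage (1e-3 for segmentation pretraining and the capacity check). The
  published 8e-5 is tuned to a 25M-parameter network on 19k images; for a
  64k-parameter network on 200 phantoms a proportionally larger step is
  standard, and the larger batch follows the published observation that
  decoupled alternating training frees memory for bigger batches, which
  also smooths the small-sample gradient noise. The package default
  remains 8e-5 / 16.
* Segmentation pretraining: 64 phantoms, 10 epochs; Dice evaluated on 32
  held-out phantoms (hard Dice at threshold 0.5).
* Classification: a 200-phantom dataset (hash splits ≈140/30/30),
  24 alternating epochs starting with the main component; the
  best-validation checkpoint (earliest strict improvement) is the
  retained model.
* The overfitting capacity check uses 32 phantoms at 32×32 and stops as
  soon as running training accuracy reaches 100%.

Under these conditions the pretrained encoder-decoder reaches held-out
Dice ≈ 0.95, alternating training reaches 80–95% validation accuracy on
the phantom task (well above the same weights with attention disabled),
and on every correctly classified validation phantom
the mean bounded attention inside the lung mask exceeds the mean outside
— the package's quantitative stand-in for the published qualitative
observation that global attention concentrates on the lung fields.

## Numerical and engineering notes

No deep-learning framework is used: the package carries its own small
reverse-mode autodiff tape with C++ kernels (im2col + GEMM convolution,
2×2 max-pooling with argmax scatter, half-pixel bilinear resampling with
exact adjoint). Gradients are verified against central finite differences
in the test suite. Determinism: every stochastic step draws from an
isolated, seeded RNG stream (the caller's RNG state is saved and
restored), so histories, datasets and checkpoints are reproducible from
`(config, seed)`; training-history comparisons in the tests use a 1e-7
tolerance to stay robust to BLAS reduction-order differences.

Degenerate inputs are handled explicitly: undefined metrics (no positive
samples, or no positive calls) raise errors from the strict metric
functions but appear as `NA` in evaluation reports; a spatially constant
activation map normalizes to all zeros for display; bounded maps stay in
(0, 1) through resizing by convexity.

Known limitations: batch statistics (batch normalization) are absent, so
very deep backbones train more slowly than their framework-native
counterparts; the `resnet50` backbone is architecture-faithful
(bottleneck residual stages 3-4-6-3) but normalization-free and is
intended for structure experiments rather than full-scale training; and
published benchmark accuracies on external cohorts are out of scope —
they require those cohorts and GPU-scale training.
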