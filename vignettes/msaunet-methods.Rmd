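---
title: "Methods: multi-scale spatial attention U-Nets for small-organ CT segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale spatial attention U-Nets for small-organ CT segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msaunet)
```

## The problem

Gallbladder segmentation in abdominal CT is hard for three compounding
reasons: the organ is small (a few hundred pixels on a 2-D slice), its shape
is irregular and variable, and its gray-level contrast against neighboring
soft tissue (liver parenchyma, duodenum) is low — often within one noise
standard deviation. Plain U-Nets with a single kernel size and no spatial
re-weighting tend to under- or over-segment in this regime. `msaunet`
implements a U-Net family whose encoder stages are augmented with
*Multi-Spatial-Attention (MSA) blocks* that combine multi-scale feature
extraction with multi-scale spatial gating, along with everything needed to
exercise the architecture end to end: a seeded CT-like phantom generator,
Hounsfield-unit preprocessing, a Dice loss, a seven-metric evaluation
suite, and ANOVA/LSD model comparison.

## Model

### MSFEF: multi-scale feature extraction and fusion

Each MSFEF module runs parallel same-padding convolution branches with odd
kernel sizes (bank A: 3, 5, 7; bank B: 5, 7, 9), each producing
`out_channels` features through conv–BN–ReLU, and fuses the concatenated
branches with a 1×1 conv–BN–ReLU back to `out_channels`. Fusion by
concatenation plus 1×1 convolution (rather than summation) lets the model
learn how to weight the scales; the branch width equals the output width.
Both choices are open in the source description and are recorded here as
package decisions.

### sSE and MSSA attention

The channel-squeeze/spatial-excitation (sSE) gate is a 1×1 convolution
squeezing channels to one, followed by a sigmoid; the resulting per-pixel
weight map in (0, 1) multiplies every channel. MSSA extends this with one
attention map per pooled scale: the input is average-pooled by factors 2
and 4, each pooled map passes a 3×3 convolution and sigmoid, and is
bilinearly upsampled back to input size. The sSE map and the two per-scale
maps are concatenated and fused by a final 3×3 convolution + sigmoid into
the gating weights. Pool factors (2, 4) give two genuinely distinct scales
with exact cheap upsampling; the fusion operator (concatenation + conv) is
again a package decision where the source only says "fused". We read the
"features obtained from the sSE mechanism" entering the fusion as the sSE
*weight map* (not the recalibrated tensor), because the fusion output is a
set of attention weights — a single-channel object.

Two consequences are used as test invariants: all attention weights lie
strictly in (0, 1) for finite inputs, and recalibration is an elementwise
contraction, `|x ⊙ w| ≤ |x|`.

### The MSA block and the two model versions

An MSA block is MSFEF → spatial attention → residual shortcut. V1 uses a
single MSFEF (bank A); V2 runs two parallel MSFEFs (banks A and B) whose
outputs are concatenated and fused 1×1 before attention. A channel
mismatch on the shortcut is handled by a learned 1×1 projection; with
matching channels the shortcut is the identity, so zeroing every learned
weight makes the block an exact pass-through (a wiring test).

### Backbone

The U-Net encoder has `depth` stages (default 4) of width
`base_channels * 2^(s-1)` (default base 32), each followed by 2×2
max-pooling, then a double-convolution bottleneck. The deepest
`n_msa_blocks` encoder stages use MSA blocks in place of the standard
double convolution, filling upward from the stage just above the
bottleneck as the count grows; the exact insertion points are not pinned
in the source and this placement is our recorded choice. Defaults are the
configurations found optimal with MSSA: 3 blocks for V1, 2 for V2. The
decoder upsamples bilinearly (avoiding checkerboard artifacts of strided
transposed convolutions), halves channels with a 3×3 conv–BN–ReLU,
concatenates the skip, and applies a residual double convolution; batch
normalization follows every convolution, per the stated decoder
improvements. A final 1×1 convolution + sigmoid yields per-pixel
probabilities; the model is strictly 2-D slice-wise (the source shows 2-D
segmentations and never describes 3-D context).

`n_msa_blocks = 0` is the improved-U-Net baseline. Total parameter count
is strictly increasing in `n_msa_blocks`, and V2 exceeds V1 at equal
widths — both are asserted in the acceptance suite.

### Why a built-in autodiff engine

No deep-learning framework is available in the target R environment, so
the package ships a small reverse-mode autodiff engine over dense arrays
(layout H×W×C×N) with Rcpp/Armadillo im2col convolutions. Every primitive
(convolution, batch norm, pooling, bilinear resampling, gating, the Dice
loss node) is verified against central finite differences in the test
suite; batch norm uses biased variance for normalization and running
statistics, and Adam is the only optimizer.

## Loss

The soft Dice loss is `1 − 2(|GT ∩ Pred| + ε) / (|GT| + |Pred| + ε)` with
soft intersection `Σ gt·pred`. As printed, ε appears once in the numerator
*inside* the doubling and once in the denominator, which makes the
empty-ground-truth/empty-prediction case evaluate to −1 rather than 0.
The default follows this literal form (fidelity first — it only matters
for slices with no foreground anywhere); `symmetric_eps = TRUE` switches
to `1 − (2·I + ε)/(G + P + ε)`, which returns 0 for the empty–empty case.
ε defaults to 1e-6 (no value is published). For fixed nonempty ground
truth the loss is minimized exactly at the ground truth, and any single
flipped pixel strictly increases it — verified by brute force on 8×8
grids.

## Phantom generator: the stated world

No image data are published (the patient cohort is private), so the
package generates CT-like phantoms that reproduce the *regime*, not the
anatomy:

* **Target**: a perturbed ellipse. The elliptical radius is modulated by a
  truncated Fourier series (first four harmonics, random amplitudes and
  phases, normalized so the relative perturbation never exceeds
  `irregularity`). `irregularity = 0` is an exact discretized ellipse,
  which anchors an area oracle (π·a·b within 5%).
* **Confusability**: `n_neighbors` disjoint elliptical blobs whose mean
  intensity sits within ±10 HU of the target (default +8 HU), emulating
  the gray-level similarity of adjacent organs.
* **Intensities**: liver-like background 60 HU, bile-like target 20 HU,
  additive Gaussian noise of 15 HU — typical portal-venous soft-tissue
  values; chosen once and not tuned.
* **Determinism**: a `phantom_spec` with the same seed is byte-identical;
  dataset generation derives independent sub-seeds per case.

The generator does **not** model scanner physics, partial-volume effects,
textured parenchyma, or 3-D continuity. A green learnability test
therefore establishes that the implementation can fit a small, irregular,
low-contrast target among gray-similar distractors — not that it matches
clinical performance numbers, which the specification explicitly excludes
from machine-checkable targets.

The train/validation/test split rule reproduces the published partition:
validation and test sizes are rounded up toward the 7:1:7 ratio and
training takes the remainder, so 152 cases give (70, 11, 71) — note this
is *not* the largest-remainder apportionment, which would give 71/10/71.

## Preprocessing

HU conversion is the standard affine rescale. The default display window
(center 50 HU, width 400 HU) is a conventional abdominal soft-tissue
window; the study states that windowing was tuned for liver/gallbladder
contrast without publishing values, so the window is configurable and the
default documented. Adaptive histogram equalization is CLAHE-style: an
8×8 tile grid, 256 bins, clip limit 0.01 of the tile pixel count with
uniform redistribution of the excess, and bilinear interpolation between
tile mappings. Augmentation (rotation ±15°, shift ±10%, shear ±5°, zoom
0.9–1.1 by default) samples one affine map per pair and applies it to
image (bilinear, out-of-frame filled with the image minimum) and mask
(nearest-neighbor, filled with 0) identically.

## Metrics

DSC, JSC, PPV and SE are computed from pixel-set counts; RVD is
absolute-valued (all published values are non-negative) and VOE is
1 − Jaccard. The Hausdorff distance runs over 8-connected boundary
pixels under the Euclidean pixel metric (the published unit is unstated;
pixels are used), with an optional percentile variant (e.g. HD95).
Degenerate cases follow a flag-don't-crash policy: an empty prediction
yields zero overlap metrics and the image-diagonal Hausdorff fallback,
flagged and excluded from aggregates where undefined (`NA`). Every metric
is checked against an independent brute-force oracle on random mask pairs
to 1e-9.

## Statistics

`one_way_anova()` is the classical decomposition with p from the F
distribution, plus Fisher LSD pairwise t-tests from the pooled
within-group mean square. The two-stage protocol (LSD interpreted only
under a significant omnibus F at α = 0.05) is expressed in the
`significant` column rather than by withholding the table: the pairwise
statistics are always computed, because the magnitude of mean differences
is useful descriptively even when the gate fails. `mean_diff` is reported
as a magnitude; the sign lives in the t statistic. Group confidence
intervals are t-based. The type-I error of the omnibus gate is calibrated
by simulation in the acceptance suite (4 groups × 30 null draws, 2000
simulations, rejection rate within [0.04, 0.06]).

## Numerical and scale choices

* Training defaults (Adam, lr 1e-3, batch 8) are repository policy; the
  published hyperparameters live in unavailable supplementary material.
* The acceptance-grade learnability run is scaled for a single-CPU
  budget: 64×64 phantoms, base width 8, depth 3, 10 epochs over 200
  training cases (~4 minutes). It reaches mean held-out DSC ≈ 0.94
  against a bar of 0.85; epochs were fixed from the time budget, not
  tuned to the bar.
* MSSA requires spatial dimensions divisible by the pool factors; the
  builder's stage sizes guarantee this for power-of-two inputs ≥
  `2^depth * 4`. No internal padding is implemented.
* Checkpoints embed the full model configuration, weights, batch-norm
  running statistics and preprocessing settings, so evaluation is
  self-contained.
* All randomness flows through explicit seeds; generation, training and
  evaluation are bit-reproducible on a single device.

## Known limitations

* 2-D slice-wise only; no 3-D context, no DICOM tag reading (rescale
  slope/intercept are passed explicitly), no multi-GPU.
* The comparison models of the original study (TransUNet, Swin-Unet,
  Attention U-Net) are third-party architectures and out of scope.
* PNG output is 8-bit (the optional `png` package does not expose 16-bit
  writing); the 16-bit plain carrier is PGM and the floating-point
  carrier is single-slice NIfTI-1.
* Published cohort-level metric values cannot be reproduced without the
  private data; the package's quantitative claims are confined to what
  its own tests compute on phantoms.
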