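---
title: "CASNet: model, losses, metrics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CASNet: model, losses, metrics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casnet)
```

## The segmentation problem

Short-axis cardiac MRI segmentation assigns each pixel of a grayscale slice
to one of four classes: background, right ventricle (RV), myocardium (MYO)
or left ventricle (LV). Two failure modes dominate plain encoder–decoder
networks on this task: fixed receptive fields that miss the large
scale variation between basal and apical slices, and naive skip connections
that concatenate low-level encoder texture onto high-level decoder
semantics. A third, loss-side problem is that pixel-wise objectives (Dice,
cross-entropy) say nothing about boundary geometry, so predicted contours
can be jagged even when overlap is good.

CASNet addresses all three inside a standard U-Net backbone:

1. **Multi-Scale Context Block (MSCB)** at the bottleneck. The deepest
   encoder map $F_{in} \in \mathbb{R}^{C\times H\times W}$ passes through
   parallel $1{\times}1$, $3{\times}3$ and $5{\times}5$ convolutions (each
   $C \to C$, ReLU-activated, padded to preserve spatial size); the three
   outputs are concatenated to $3C$ channels and fused back to $C$ by a
   $1{\times}1$ convolution. The block changes neither spatial size nor
   channel count, so it can be toggled without touching the rest of the
   architecture.

2. **Cross-Attentive Skip Connections (CASC)** at every decoder level.
   The upsampled decoder map provides queries, the same-resolution encoder
   map provides keys and values, all through learned $1{\times}1$
   projections into a shared $C_a$-dimensional embedding. Attention weights
   are the row softmax of $\langle Q_i, K_j\rangle / \sqrt{C_a}$ over key
   positions $j$; the attended values are concatenated with the decoder map
   and fused by a $3{\times}3$ convolution back to the decoder width. Each
   attended feature is a convex combination of value vectors, which the
   test suite checks directly.

3. **Curvature-aware loss.** The training objective is
   $\lambda_1 L_{BCE} + \lambda_2 L_{Dice} + \lambda_3 L_{curv}$ with
   default weights $(0.5, 0.4, 0.1)$. The curvature term is the mean
   squared Frobenius norm of the spatial Hessian of each foreground
   probability map,
   $L_{curv} = \tfrac{1}{HW}\sum_{i,j}\lVert\nabla^2\hat Y(i,j)\rVert_F^2$,
   computed with central second differences. It penalises high-frequency
   wiggles in the probability surface and therefore in the decision
   boundary; smoothing a jagged mask strictly decreases it, which is one of
   the package's acceptance properties.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `depth` | 4 (3 at desk scale) | resolution levels of the backbone |
| `baseChannels` | 32 (16 at desk scale) | channels at the first level, doubling per level |
| `attentionPoolThreshold` | 1024 | max key/value positions before average pooling |
| loss weights | 0.5 / 0.4 / 0.1 | BCE / Dice / curvature balance |
| learning rate | 1e-4 | Adam, betas (0.9, 0.999) |
| schedule | halve on a >10-epoch validation plateau | plateau tolerance 1e-5 |
| batch size | 8 | minibatch size |
| Dice smoothing `s` | 1 | keeps the ratio defined on empty masks |
| BCE clip $\epsilon$ | 1e-7 | bounds the log terms |

The channel widths, depth and normalisation layers are standard U-Net
practice; each conv is followed by batch normalisation and a rectifier.
Upsampling uses 2×2 transposed convolutions for symmetry with the 2×2
max-pool downsampling. Attention is single-head, and $C_a$ defaults to half
the encoder width at that level.

### Attention tractability

Full-resolution spatial attention costs $O((HW)^2)$ memory. Queries always
stay at full resolution — the output grid of the attended features is never
changed — but keys and values are average-pooled by the smallest
power-of-two factor that brings their count under
`attentionPoolThreshold`. The default threshold of 1024 means a 256×256
level attends over a 32×32 key grid (a 64:1 key:query ratio). The
desk-scale configuration used by the test suite sets the threshold to 64 so
that 64×64 inputs attend in the same 64:1 regime (8×8 keys); keeping the
key:query ratio matched across scales makes desk-scale behaviour
representative of the full-scale pooling regime while staying cheap.

## Multi-class extension of the losses

The curvature and Dice formulations are stated for a single binary map. The
package applies each term per foreground class and averages: background is
excluded from Dice and curvature (its probability surface is the complement
of the union of foreground classes, so penalising it would double-count)
but included in BCE, where every class map is an independent binary
problem. For two classes this reduces exactly to the binary form. The
per-class curvature terms are each normalised by $HW$; the mean over
foreground classes keeps the weight $\lambda_3$ comparable across values of
$K$.

Whether curvature should apply to the raw softmax channels or a single
foreground map is not determined by the formulation; applying it per
foreground channel is the choice here because each anatomical structure's
boundary should be smooth individually.

## Evaluation metrics

Seven metrics are computed per foreground class and macro-averaged: Dice
$2TP/(2TP+FP+FN)$, recall, accuracy, precision, Jaccard, the exact
(100th-percentile) Hausdorff distance, and the mean absolute contour
distance (MAD), the average nearest-neighbour distance from predicted to
true contour points. MAD is one-directional as printed in its defining
formula; a symmetrised variant is available via `symmetric = TRUE`.
Contours are foreground pixels with a 4-connected background neighbour (or
on the image edge), with pixel centers as coordinates and distances scaled
by the pixel spacing in mm.

Empty-mask conventions: if both masks lack the class, overlap metrics score
1 and distances 0 (perfect agreement about absence); if exactly one is
empty, the distances are undefined and reported as `NA` with a warning,
and macro averages exclude them. This keeps single degenerate cases from
contaminating aggregate tables with infinities.

## The phantom generator

`generatePhantom()` emulates a short-axis slice: a bright elliptical LV
blood pool (intensity 0.80) nested in a darker myocardial annulus (0.35),
with an attached RV crescent (0.50) on a 0.20 background, plus a smooth
random bias field (amplitude 0.3, a 4×4 control grid bilinearly upsampled)
and additive Gaussian noise (sd 0.1). The LV ellipse has axes $rs$ and
$r/s$ with aspect $s \in [0.85, 1.15]$, so its area is exactly $\pi r^2$
for the drawn radius — convenient for geometry tests. The noise and bias
levels were fixed once, at values where plain intensity thresholding fails
(class means are closer together than the bias-field swing), so that
context and capacity matter for segmentation.

What the phantom does **not** emulate: pathology-specific shape variation,
papillary muscles, through-plane anatomy changes, partial-volume effects at
boundaries, coil-specific noise correlation, or temporal (cine) structure.
Passing the phantom suite therefore demonstrates that the architecture,
losses, metrics and training loop are implemented correctly and interact as
designed — not that the trained weights would transfer to clinical MRI.

Augmentation follows the training protocol: horizontal/vertical flips
(probability 0.5 each), rotations uniform in 0–15°, isotropic scaling in
[0.9, 1.1], and an elastic deformation parameterised as a 4×4 random
displacement grid with maximum displacement 5% of the image size,
bilinearly upsampled — a standard fully seed-controlled construction. One
geometric map is applied bilinearly to the image and nearest-neighbour to
the mask, so labels are preserved exactly.

## Numerical choices

* **Precision.** Convolution and attention GEMMs run in single precision by
  default (`options(casnet.fp32 = FALSE)` switches to double), the standard
  training precision for this model family; forward passes agree with the
  double path to ~1e-7. The finite-difference gradient tests use the double
  path.
* **Hessian stencils.** Central differences, exact on quadratics (the tests
  exploit this), with replicate padding at the borders; an interior-only
  evaluation is available for analytic checks. The squared Frobenius norm
  sums all four entries of the 2×2 Hessian, counting the mixed partial
  twice.
* **Softmax.** Computed with the max-subtraction trick; per-pixel argmax
  ties break toward the lower class index (`ties.method = "first"`).
* **Determinism.** Every random quantity — phantom geometry, weight
  initialisation, shuffling, augmentation draws — derives from a single
  experiment seed through independent child seeds, and the RNG state of the
  caller is always restored. Two runs with the same seed are bitwise
  identical.
* **Degenerate inputs.** Images smaller than 32 px are rejected by the
  phantom spec; spatial sizes not divisible by $2^{depth-1}$ are rejected
  by the forward pass; masks with labels outside the class table are
  rejected at read time with the offending label named.

## Training harness

Adam (lr $10^{-4}$, betas 0.9/0.999), batch size 8, with the composite
loss. A fraction (default 12.5%) of the training set is held out for
validation: it drives the plateau-based learning-rate halving and selects
the best checkpoint (lowest validation composite loss), which is what
`trainModel()` returns. The validation construction is a design choice —
the protocol only fixes an 80/20 train/test split — and the composite loss
is used as the selection criterion because no other criterion is named.

The desk-scale defaults — 64×64 phantoms, depth 3, 16 base channels, 15
epochs, 128 training and 64 test phantoms — are small enough to train on a
single CPU core in about two minutes per variant while leaving the
paper-scale settings (256×256, depth 4, 150 epochs) reachable through the
configuration. At these sizes both the baseline and the full model are
still clearly improving when training stops; the ablation should be read as
an ordering check under matched conditions, not as converged performance.

## Ablation runner

`runAblation()` trains on/off combinations of (MSCB, CASC, curvature term)
on the same phantom split with the same seed and reports the seven metrics
on the shared test set. A variant with the curvature term off sets
$\lambda_3 = 0$ and leaves the other weights untouched. The double-off
variant is exactly the plain U-Net baseline — the test suite asserts
parameter-count equality with an analytic formula.

## Known limitations

* 2D slices only; no 3D convolutions or cine/temporal modelling.
* Single-head attention; no transformer baselines.
* The phantom task is far easier than clinical MRI; desk-scale DSC values
  are not comparable to published benchmark numbers, and at 15 epochs the
  models are deliberately undertrained.
* Batch-norm running statistics make validation losses drift slightly even
  under frozen weights, which is why the learning-rate scheduler is
  unit-tested on synthetic loss sequences.
* The exact Hausdorff distance is sensitive to single stray pixels; no
  HD95 variant is provided because the evaluation protocol specifies the
  exact form.
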