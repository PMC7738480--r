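---
title: "Multi-view cortical plate segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view cortical plate segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cpseg)
```

## The problem

The cortical plate (CP) of the fetal brain is a thin (1–3 voxel at the
0.75 mm reconstruction grid), heavily folded band of developing gray
matter. Quantifying its volume and folding across gestation requires a
segmentation that is accurate specifically at the CP's boundaries, where
partial-volume blur makes voxel labels ambiguous. `cpseg` implements a
2.5D deep-learning pipeline for this problem: three independent 2D
fully convolutional networks — one per orthogonal plane — are trained on
slices, and their flip-augmented softmax outputs are summed across planes
at test time ("MVT": multi-view aggregation with test-time augmentation).
The package also provides the matching evaluation metrics and
surface-based morphometry, and a parametric phantom generator so that the
complete pipeline is testable without patient data.

## Labels and geometry

Volumes are arrays indexed (x, y, z), x running left to right. The label
scheme is 0 background, 1/2 left/right inner volume of the CP (all tissue
enclosed by the CP's inner boundary), 3/4 left/right CP. Axial slices are
(x, y) planes, coronal (x, z), sagittal (y, z); the first in-plane axis of
axial and coronal slices is therefore the left–right axis, which defines
what a "horizontal" flip means. Sagittal slices cannot see laterality, so
the sagittal network is trained on a merged 3-label scheme
(background / inner / CP).

## Network

Each plane network is an encoder–decoder with skip connections. A block
is three repetitions of *batch-norm → ELU → 3×3 zero-padded convolution*
(pre-activation ordering); blocks are separated by 2×2 max-pooling with
stride 2 on the way down and 3×3 transposed convolutions with stride 2 on
the way up, each upsampled map concatenated with the final feature map of
the same-size encoder block. A 1×1 convolution and a softmax produce
per-pixel label probabilities. The full-scale configuration starts at 32
feature maps and doubles per level to 512 at depth 4; the 3D comparison
variant uses the same topology with 3D layers, starting at 8 and peaking
at 128. Initialization is seeded He-uniform; with a fixed seed the whole
training run is bit-reproducible.

The engine is implemented in the package itself (RcppArmadillo kernels:
im2col + GEMM convolutions, their adjoints, pooling with argmax routing,
batch-norm, ELU, softmax, Adam). Analytic gradients of every layer and
loss are verified against central differences in the test suite.

## Loss family

With per-label smoothed Dice
\(D_l = (2\sum_i g_{li} p_{li} + \epsilon)/(\sum_i (g_{li}+p_{li}) + \epsilon)\),
pixels pooled over the batch:

* basic Dice loss: \(1 - \frac{1}{N_l}\sum_l D_l\);
* focal (exponential-logarithmic) Dice loss:
  \(\frac{1}{N_l}\sum_l (-\ln D_l)^{\gamma}\) with \(\gamma = 0.3\),
  which up-weights labels that are currently segmented poorly;
* hybrid loss: the focal loss on the full maps plus
  \(\lambda = 0.1\) times the focal loss computed on erosion residuals
  \(x - (x \ominus B)\), where \(B\) is a flat disk of diameter 7
  (offsets with Euclidean distance ≤ 3), eroded per 2D slice in
  grayscale with replicated borders. The residual of a binary region is
  a band along its inner boundary, so this term concentrates the loss on
  boundary pixels.

Numerical choices: \(\epsilon = 10^{-5}\) in numerator and denominator;
the logarithm argument is clamped to \([\epsilon, 1]\); the boundary term
reuses \(\gamma\) and includes the background label (a flag can exclude
it); the gradient of the erosion routes through the per-pixel argmin,
exactly like max-pooling. Two caveats discovered while testing are worth
recording. First, \(|\partial L/\partial D|\) of the focal loss is not
monotone in \(D\): it diverges again as \(D \to 1\), so the "weaker label
gets the larger gradient" property holds in the under-segmentation regime
(roughly \(D < 0.5\)) where it matters, not uniformly. Second, with
grayscale erosion an isolated interior error spawns an erosion shadow and
therefore *is* a boundary error from the morphology's point of view; the
boundary term is best understood as amplifying contour misplacement (a
1-pixel shift barely moves whole-map Dice but sharply degrades the
residual-band Dice), not as ignoring interiors.

## Aggregation

At test time each plane is predicted under spatial flips — 4 variants
(identity, horizontal, vertical, both) for axial and coronal, 3 for
sagittal — and each output is inverse-transformed before summation. A
horizontal flip of an axial or coronal slice exchanges anatomical left
and right, so inverting it also swaps the paired label channels (1↔2,
3↔4). The sagittal plane has no laterality and never swaps; its 3-label
probabilities are broadcast to both hemispheres' channels (the inner
probability is added to both left- and right-inner, likewise CP). The
final label is the per-voxel argmax of the summed probabilities — 11
predictions for MVT (4 + 4 + 3), 3 for multi-view, 4 for single-plane
TTA, 1 for a single plane — with ties broken toward the lowest label
index so that background wins exact ties deterministically. Probabilities
are summed raw, never renormalized: argmax is invariant to the common
scale, and the sagittal broadcast intentionally double-counts.

Which sagittal flip variant to drop (to keep 11 predictions) is not
dictated by the aggregation rule; we drop the combined
horizontal+vertical flip and keep {identity, horizontal, vertical}. The
flip set is configurable.

## Training protocol

Ten-fold cross-validation with stratified sampling on the folding
complexity (the gestational-age surrogate in phantoms) is the full-scale
protocol; 10 % of the training cases — cases, not slices, to avoid
intra-case leakage — form the validation set, stratified the same way.
Training uses Adam (full-scale learning rate \(10^{-4}\)), flip
augmentation matching the TTA flips (with label swap on left–right
flips), and early stopping on the validation Dice (mean over foreground
labels of the pooled hard Dice), keeping the best-scoring weights.
Batch-norm uses batch statistics during training and running averages at
inference, so prediction is deterministic.

## The phantom generator

Each phantom is two non-overlapping "hemispheres": an ellipsoidal inner
compartment wrapped in a shell of constant radial thickness (default
1.5 mm) whose outer boundary is corrugated by
\(A \sin(f\theta)\sin(f\varphi)\) in spherical angles. The corrugation
amplitude is the folding-complexity dial: complexity \(c \in [0,1]\) maps
to \(A = c \cdot A_{max}\), where \(A_{max}\) keeps the folds inside the
inner compartment and clear of the mid-sagittal plane. Intensity is the
label-mean image (background 0, inner 1.0, shell 0.45 — CP-like contrast
on T2-weighted-like data), blurred with a separable Gaussian
(default FWHM 1.2 mm, emulating partial volume) plus i.i.d. Gaussian
noise (sd 0.1). Left/right is decided by the mid-sagittal grid plane,
plane voxels going left.

What the phantoms do *not* emulate: fetal motion and
slice-to-volume reconstruction artifacts, bias fields, Rician noise,
deep-sulcal CSF, anatomical asymmetry, or the gyral geometry of a real
cortex (the corrugation is a separable sinusoid). Passing the scaled-down
recovery tests therefore demonstrates that the implementation of the
method is sound — losses, training, aggregation and metrics interact
correctly — not that the reported clinical accuracies transfer; those were
measured on fetal MRI that is not distributable with this package.

## Metrics and morphometry

Evaluation uses the Dice coefficient (both-empty regions score 1, exactly
one empty scores 0) and a symmetric mean surface distance: boundary
voxels are region voxels with a face-adjacent non-region neighbor,
distances come from an exact Euclidean distance transform, and the two
directed means are averaged. For morphometry the binary inner compartment
is smoothed with a 1.5 mm FWHM Gaussian, an isosurface is extracted at
0.5 by marching tetrahedra on the Kuhn 6-tetrahedra cube decomposition
(watertight by construction; verified via discrete Gauss–Bonnet,
\(\sum\) angle deficits \(= 4\pi\)), and the mesh is smoothed with 10
volume-preserving Taubin iterations (\(\lambda = 0.5, \mu = -0.53\)).
Per-vertex areas use Meyer's mixed-Voronoi rule, so they partition the
faces exactly; per-vertex curvature is the angle deficit normalized by
that area ("angular deviation"), and the global mean curvature is the
area-weighted mean of its absolute value. The angular-deviation reading
of curvature is one of two defensible discretizations (the other being a
mean-curvature-normal magnitude); it lives behind a single function so
the alternative is swappable.

## Desk-scale problem sizes

Everything the package's tests and the acceptance script run is sized for
a single CPU:

* tiny preset (`tiny_experiment_config()`): 16 phantoms on a 64³ grid,
  base-8 depth-3 networks on 64×64 slices, 3 stratified folds, batch 8.
  The learning rate is raised to \(2\times10^{-3}\) because the
  scaled-down runs take orders of magnitude fewer optimizer steps than
  the full protocol; with it, held-out MVT CP Dice reaches ≈ 0.86–0.94
  within 2–3 epochs on phantoms.
* the acceptance tests train 2 epochs per plane with background-only
  slices subsampled to 25 % per epoch (they stay in training — the
  network must learn to emit background — but need not all be revisited
  every epoch), and evaluate 2–3 held-out cases per seed; the basic-Dice
  versus hybrid loss comparison is run on the axial plane under TTA,
  since the loss effect is a property of per-plane training.
* micro configurations in the unit tests (4 phantoms at 32³, base-4
  depth-2 networks) exist purely to exercise the machinery.

## Known limitations

* The corrugated-shell phantom is rotationally structured; real cortical
  folding is not, and phantom Dice values are optimistic relative to
  fetal MRI.
* The 3D network variant is implemented and shape/gradient-verified, but
  the packaged experiment drivers train 2D plane networks only.
* No CSF label, hence no outer-CP surface or cortical thickness.
* The engine is CPU-only and double-precision; it is built for
  correctness and desk-scale experiments, not for production GPU
  training.
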