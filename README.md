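# cpseg — fetal cortical plate segmentation with multi-view aggregation

`cpseg` segments the **cortical plate (CP)** — the thin, folded band of
developing gray matter — and the inner volume it encloses from
reconstructed, template-aligned T2-weighted-like fetal brain volumes
(0.75 mm isotropic grid, 5 labels: background, left/right inner volume,
left/right CP). It is aimed at researchers quantifying fetal cortical
development (CP volume, surface area, folding) who need an automatic,
reproducible segmentation pipeline plus the matching morphometry.

## Method

Three independent 2D encoder–decoder networks (one per orthogonal plane;
blocks of batch-norm → ELU → 3×3 convolution in triplicate, 2×2
max-pooling, transposed-convolution upsampling with skip connections,
softmax over 5 labels — 3 for the sagittal plane, which cannot see
laterality) are trained on slices with a **hybrid Dice loss**

```
L_hyb(g, p) = L_focal(g, p) + λ · L_focal(g − g⊖B, p − p⊖B),
L_focal(g, p) = (1/N_l) Σ_l (−ln D_l)^γ,
D_l = (2 Σ_i g_li p_li + ε) / (Σ_i (g_li + p_li) + ε),
```

with γ = 0.3, λ = 0.1 and B a flat disk of diameter 7: the focal
(exponential-logarithmic) term re-weights poorly segmented labels, and
the erosion-residual term concentrates the loss on boundary bands. At
test time each plane is predicted under spatial flips (4 axial + 4
coronal + 3 sagittal = 11 predictions; left–right flips swap the paired
label channels on inversion), the sagittal 3-label output is broadcast to
both hemispheres, and the summed probabilities are argmaxed per voxel
(**MVT** — multi-view aggregation with test-time augmentation).

Evaluation uses the Dice coefficient and a symmetric mean surface
distance (exact Euclidean distance transform); morphometry extracts the
inner-CP surface by marching tetrahedra after 1.5 mm FWHM smoothing,
Taubin-smooths it, and reports CP volume, mixed-Voronoi surface area and
the global mean curvature (area-normalized angle deficit).

Because clinical fetal MRI cannot be shipped, the package includes a
seeded **folded-shell phantom generator** (two corrugated ellipsoidal
shells with CP-like contrast, partial-volume blur and noise; corrugation
amplitude is a gestational-age-like complexity dial) on which the whole
pipeline — training included — runs end to end on a desk CPU. The
network engine itself (convolutions, pooling, batch-norm, Adam, backprop)
is implemented in the package with RcppArmadillo kernels; analytic
gradients are verified against finite differences in the tests.

## Worked example

```r
library(cpseg)

## a phantom "subject": two corrugated hemispheres at 0.75 mm
spec <- phantom_spec(grid_shape = c(64, 64, 64), fold_amplitude_mm = 2, seed = 42)
case <- generate_phantom(spec)
case
#> Phantom case (complexity 0.92): grid 64x64x64,
#>   voxels bg/inL/inR/cpL/cpR = 243996/5554/5554/3520/3520

## surface-based morphometry of the left hemisphere
morphometry(case$labels, "left", voxel_mm = 0.75)
#>   side cp_volume_cc inner_area_mm2      gmc
#> 1 left        1.485        1078.05 0.228308

## metrics against a corrupted copy of the labels
noisy <- case$labels
noisy[noisy == 3L][seq_len(500)] <- 0L
dice3d(noisy, case$labels, "CP_L")
#> [1] 0.9235474
mean_surface_distance(noisy, case$labels, "CP_L", voxel_mm = 0.75)
#> [1] 0.1412303
```

The complexity value (0.92) is the corrugation amplitude relative to its
admissible maximum; the morphometry row gives the left CP volume in cc,
the inner-surface area in mm² and the global mean curvature. Deleting
500 of the 3520 left-CP voxels drops the CP Dice to 0.92 and produces a
mean surface distance of 0.14 mm.

Training and applying the full method on a phantom cohort:

```r
cfg <- tiny_experiment_config(seed = 1)         # 16 phantoms, 64³, base-8 nets
run <- run_experiment(cfg, modes = c("mvt", "single-axi"))
aggregate(dice ~ mode + region, run$results, mean)
```

A thin command-line front end (`inst/scripts/cpseg`) exposes
`simulate`, `train`, `predict` and `evaluate` subcommands over the same
functions.

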