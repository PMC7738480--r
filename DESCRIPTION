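Package: cpseg
Title: Fetal Cortical Plate Segmentation with Multi-View Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-plane 2D fully convolutional segmentation of the fetal
    cortical plate from reconstructed T2-weighted-like volumes, trained with a
    hybrid (focal + boundary) Dice loss and combined at test time by multi-view
    aggregation with flip-based test-time augmentation. Includes a seeded
    generator of folded-shell phantom volumes for end-to-end testing, evaluation
    metrics (Dice coefficient, mean surface distance) and surface-based cortical
    morphometry (volume, Voronoi surface area, global mean curvature) computed
    on meshes extracted from the segmented inner cortical-plate boundary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
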