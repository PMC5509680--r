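Package: mparseg
Title: Patch-Based Convolutional Segmentation of Tumours on Multiparametric MR
Version: 0.1.0
Authors@R: person("mparseg", "developers", role = c("aut", "cre"),
    email = "mparseg@example.org")
Description: Fully automatic localization and segmentation of tumours on
    co-registered multiparametric magnetic resonance volumes (T2-weighted,
    diffusion-weighted b0 and high-b). Implements intensity standardization,
    a simplified deformable B-spline registration stage, region-stratified
    class-balanced patch sampling, a nine-layer convolutional voxel
    classifier trained with Adadelta and patience-based early stopping,
    probability-map inference with threshold and largest-connected-component
    post-processing, and an evaluation suite (Dice similarity coefficient,
    voxelwise ROC AUC, intraclass correlation across repeated trainings).
    Ships a synthetic multiparametric phantom generator with ground-truth
    label maps so the whole pipeline is testable without patient data, plus
    NIfTI input/output and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
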