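Package: voxsal
Title: Explainable 3D Convolutional Classification and Atlas-Based
    Saliency Analysis for Volumetric Neuroimaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds truncated 3D residual classifiers for volumetric images
    by replicating 2D convolution kernels along the depth axis, trains them
    with seeded stratified k-fold cross-validation and harmonization
    augmentations, computes gradient-weighted class activation (GradCAM)
    saliency volumes from each subject's hold-out fold, converts them to
    regional scores through a probabilistic atlas, and runs the group-level
    statistics that connect regional saliency to clinical metrics: Kendall
    pairwise correlation with significance filtering, node scores,
    functional-network contrasts, inter-fold regression, and
    saliency-metric association. Ships a synthetic cohort generator that
    plants class-dependent regional intensity effects with network-coupled
    latent structure so the whole pipeline is testable without restricted
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
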