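Package: phenoscreen
Title: Image-Based Phenotypic Profiling and Screening Statistics for
    Neuronal High-Content Screens
Version: 0.1.0
Authors@R:
    person("phenoscreen", "developers", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for image-based phenotypic
    profiling of iPSC-derived midbrain dopaminergic neurons in 384-well
    plates: synthetic plate and field-image generation with ground truth,
    segmentation and per-well feature extraction over fixed staining-panel
    catalogues, preprocessing (per-plate median normalization, robust
    outlier-well removal, correlated-feature pruning), two-class reference
    classification (LDA, linear SVM, gradient-boosted trees) with repeated
    shuffled-split cross-validation and decision-space mapping of further
    conditions, and screening statistics (Z-factor, leave-one-feature-out
    attribution, 3-SD hit calling, replicate-power analysis, group tests,
    bootstrap intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
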