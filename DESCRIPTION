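Package: NoduleRadiomics
Title: Radiomic Classification of Indeterminate Pulmonary Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Three-dimensional radiomic characterization of pulmonary nodules
    on low-dose CT and a statistical pipeline for benign/malignant
    classification. Implements a 57-feature panel (location, size, bulk shape,
    Hounsfield-density statistics, texture-exemplar distributions of the nodule
    and its 10 mm surrounding lung shell, triangulated-surface curvature
    descriptors and surface-exemplar distributions), the SILA ordinated-exemplar
    aggression score based on a Cramer-von Mises distance, LASSO stability
    selection with a logistic refit, optimism-corrected bootstrap validation
    with Youden cutoffs, ablation and size-subset analyses, and synthetic
    nodule phantoms and cohort feature tables for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    glmnet,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
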