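Package: radart
Title: MRI Radiomics Pipeline for Pretreatment Prediction of Adaptive
    Radiotherapy Eligibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end MRI radiomics analysis for predicting which
    nasopharyngeal-carcinoma patients will need adaptive re-planning during
    radiotherapy, exercised entirely on synthetic phantom cohorts.
    Implements isotropic resampling, bias-field correction,
    reference-region intensity normalization, fixed-bin-width
    discretization and multi-scale Laplacian-of-Gaussian filtering; a
    479-feature extractor (shape, first-order, and GLCM/GLRLM/GLSZM/
    GLDM/NGTDM texture families); Pearson redundancy pruning and
    frequency-of-occurrence LASSO screening; and class-balanced double
    cross-validation with nested lambda tuning and AUC-distribution
    reporting for CET1-w, T2-w and joint T1-T2 model variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    RNifti,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
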