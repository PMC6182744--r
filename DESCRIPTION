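Package: ostex
Title: Subchondral Bone MRI Texture Analysis for Knee Osteoarthritis Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying subchondral bone texture on knee
    MRI as a biomarker of radiographic osteoarthritis progression. Computes
    grey-level histogram, absolute gradient, run-length matrix and grey-level
    co-occurrence matrix texture features over manually defined regions of
    interest; screens features by inter-observer reproducibility (two-way
    random-effects absolute-agreement ICC and root-mean-square coefficient of
    variation); classifies progression from minimum medial joint space width
    change and builds a 1:1 optimally propensity-matched case-control cohort;
    and derives a composite texture score by repeated cross-validated LASSO
    logistic regression, reporting odds ratios per score standard deviation
    and cross-validated c-statistics. Includes a synthetic trabecular-texture
    study generator (thresholded Gaussian random fields with Rician noise)
    so every stage can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    png,
    stats,
    utils
Suggests:
    RNifti,
    jsonlite,
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
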