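Package: petmip
Title: Outcome Prediction in Lymphoma from PET Maximum Intensity Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for predicting 2-year time-to-progression in
    diffuse large B-cell lymphoma from baseline FDG-PET scans. Generates
    coronal and sagittal maximum intensity projections (MIPs) on a fixed
    275x200 canvas, segments lesions at a SUV threshold of 4.0 and computes
    metabolic tumour volume (MTV) and the lesion dissemination feature
    Dmax_bulk, balances an imbalanced cohort with a stratified subset sampling
    scheme, trains a dual-branch convolutional network on MIP pairs under
    three transfer-training schemes, and evaluates predictions with ROC/AUC,
    the DeLong test, logistic probability calibration and a tumour-ablation
    plausibility analysis. Ships a synthetic whole-body PET phantom generator
    so the full pipeline runs without any clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
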