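Package: bonevar
Title: Variability-Aware Prediction of Bone Formation Rates by Sub-Dataset Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts not only the mean but the variability of a repeatedly
    measured response (bone formation rate of artificial calcium-phosphate
    bone substitutes) from material descriptors. Repeated measurements are
    resampled into sub-datasets, one regression model is selected and fitted
    per sub-dataset under double (nested) cross-validation, and the resulting
    per-material ensemble of out-of-fold estimates forms a predictive
    distribution. Predicted and measured distributions are summarised as
    Gaussians and scored with numerically integrated Jensen-Shannon
    divergence alongside the coefficient of determination of the means.
    Includes featurization of FT-IR/XRD spectra (band intensities), SEM-like
    images (local binary pattern histograms), Gaussian-mixture imputation of
    missing feature blocks, a synthetic-data generator emulating the assumed
    data structure, and reporting/figure utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    rpart,
    e1071,
    kernlab,
    xgboost,
    ggplot2,
    png,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
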