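Package: labimpute
Title: Comorbidity-Guided Hybrid Imputation of EHR Laboratory Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adaptive ("hybrid") imputation of laboratory measures extracted
    from electronic health records. Patients are embedded by a truncated
    singular value decomposition of their binary comorbidity (ICD) matrix,
    clustered on the resulting latent-comorbidity representation, and their
    laboratory values imputed per cluster with a chained-equations (fully
    conditional specification) engine offering predictive-mean-matching and
    random-forest conditional models. Includes a tri-modal Gaussian outlier
    filter for laboratory QC, a masking/RMSE evaluation protocol comparing
    cluster-wise against global imputation, and a synthetic EHR cohort
    generator with planted cluster structure, calibrated missingness, and a
    missing-not-at-random measurement mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
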