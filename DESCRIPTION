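Package: euscrit
Title: Inter-Rater Agreement Based EUS Criteria for Malignant Lymphadenopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for developing and evaluating endoscopic
    ultrasonography (EUS) diagnostic criteria for malignant lymphadenopathy.
    Screens categorical image features by multi-rater Fleiss kappa with
    bootstrap confidence intervals and Landis-Koch interpretation, consolidates
    five-rater assessments into per-lesion consensus features by majority vote,
    derives size cutoffs by Youden-index ROC analysis with clinical rounding,
    assembles an agreement-based three-item malignancy score, and compares it
    head-to-head against the historical four-item criteria using paired DeLong
    AUC tests and full diagnostic accuracy tables with Wilson confidence
    intervals. Includes a synthetic cohort generator that emulates the
    statistical structure of a 68-lesion EUS-FNA study, so every stage is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
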