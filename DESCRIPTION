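Package: fliscreen
Title: Fatty Liver Index Validation and Cutoff Optimization for Hepatic Steatosis Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A diagnostic-accuracy pipeline for validating the fatty liver
    index (FLI) as a noninvasive screen for hepatic steatosis. Computes the
    FLI and MDRD-estimated GFR from routine anthropometric and laboratory
    values, applies health-checkup cohort exclusions (viral hepatitis,
    significant alcohol intake, missing data), constructs binary steatosis
    reference standards from ultrasound labels or controlled attenuation
    parameter (CAP) measurements, and evaluates discrimination via ROC/AUC,
    fixed-cutoff validation, and Youden-index cutoff optimization, overall
    and stratified by sex. Includes a synthetic cohort generator with
    Gaussian-copula-joined marginal distributions so the full pipeline can
    be exercised and tested without access to subject-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
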