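Package: gfreval
Title: Creatinine-Based GFR Estimation Models and Validation Framework
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements eight serum-creatinine-based models for estimating
    glomerular filtration rate (GFR) or creatinine clearance (CamGFR,
    CKD-EPI 2009, MDRD-186, Mayo quadratic, Wright, Martin,
    Cockcroft-Gault, Jelliffe) together with the validation framework used
    to compare them against tracer-measured GFR: cohort ingestion and
    inclusion filtering, bias (median residual), precision (residual IQR),
    accuracy (RMSE) and 1-P20 statistics with normal-approximation
    bootstrap confidence intervals, paired model comparison, subgroup
    analysis, age/sex-matched group draws, carboplatin dosing via the
    Calvert equation, and a seeded synthetic-cohort generator calibrated
    to published multicenter oncology demographics.
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
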