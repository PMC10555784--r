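Package: undilute
Title: Quantify and Correct Regression Dilution Bias from Repeat Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing random and systematic measurement error in
    repeat-measured continuous variables and for correcting the resulting
    regression dilution bias in exposure-outcome and confounder-outcome
    associations. Quantifies agreement between two measurement occasions with
    intraclass correlation coefficients from a two-way mixed-effects ANOVA and
    with Lin's accuracy coefficient, derives reciprocal-ICC correction factors
    with Frost-Thompson confidence intervals, and implements two-stage
    regression calibration (for exposures and error-prone continuous
    confounders jointly) with whole-process bootstrap confidence intervals for
    linear, logistic and Cox proportional-hazards outcome models. Includes a
    synthetic cohort generator with known reliabilities, systematic shifts and
    survival outcomes, a variable-eligibility screening pipeline for repeat
    measure catalogues, and plotting and tidying methods for all result types.
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
    survival,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
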