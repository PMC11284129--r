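Package: oxbalance
Title: Oxidative Balance Score Construction and Design-Based
    Cardiovascular Risk Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds the oxidative balance score (OBS) from dietary and
    lifestyle components using sex-stratified tertile scoring, computes
    10-year atherosclerotic cardiovascular disease (ASCVD) risk with the
    ACC/AHA Pooled Cohort Equations, and provides design-based inference
    for complex survey samples: weighted logistic and Cox regression with
    Taylor-linearized stratified-cluster variance, restricted cubic
    splines with nonlinearity tests, weighted Kaplan-Meier and log-rank,
    trend and interaction tests, and a two-segment (turning-point) Cox
    model. Includes a synthetic NHANES-like cohort generator with known
    ground truth and an end-to-end analysis pipeline with an auditable
    exclusion cascade.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils
Suggests:
    foreign,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
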