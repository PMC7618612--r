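Package: pincer
Title: Pincer Morphology Measurement and Incident Hip Osteoarthritis Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for studying acetabular overcoverage
    (pincer morphology) and incident radiographic hip osteoarthritis in
    multi-cohort consortium data. Implements landmark-based automated
    measurement of the lateral centre edge angle (pelvic-tilt reference line,
    best-fit femoral head circle), morphology classification, harmonisation
    of cohort-specific osteoarthritis grades, the study inclusion cascade,
    stratified absolute and relative risk estimation from 2x2 tables, nested
    random-intercept logistic regression fitted by adaptive Gauss-Hermite
    quadrature, and a continuation-ratio ordinal model with relaxed
    ordinality. Synthetic landmark and cohort generators with known ground
    truth make every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    splines,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
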