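Package: proxymi
Title: Multiple Imputation with Linked Proxy Outcomes: A Simulation Framework
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying how a linked proxy of an
    incomplete continuous outcome, used as an auxiliary variable in multiple
    imputation by chained equations, reduces bias and improves efficiency when
    the outcome is missing not at random (MNAR). Generates synthetic
    birth-cohort data (a standardized IQ-like outcome, a breastfeeding-duration
    exposure, demographic covariates and a linked attainment-score proxy),
    imposes missingness through a linear-probability mechanism with calibrated
    intercepts, and evaluates complete-records regression against multiple
    imputation with Rubin's rules pooling (including the fraction of missing
    information) across a factorial grid of one hundred scenarios, reporting
    Monte-Carlo bias, mean squared error, empirical standard errors and
    precision gains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
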