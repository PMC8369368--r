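Package: brainnorm
Title: Multi-Ethnic Normative Modeling of Regional Brain Volumes
Version: 0.1.0
Authors@R:
    person("brainnorm", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Normative modeling of lobar and subcortical brain volumes in
    old age across ethnic groups. Fits multi-predictor norm regressions
    (ethnicity, age, sex, intracranial volume with polynomial terms,
    scanner field strength and manufacturer, and their interactions),
    scores individual subjects with single-case z-statistics based on the
    standard error of a predicted value for a new case, decomposes model
    R-squared into per-predictor contributions by averaging over predictor
    orderings, builds propensity-matched validation groups, and compares
    diagnostic classifiers built on z-scores before and after ethnicity
    adjustment with a stratified-bootstrap AUC test. Includes a synthetic
    cohort generator so the full pipeline is testable without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
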