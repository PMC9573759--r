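Package: spoturine24
Title: Spot-Urine Estimating Equations for 24-Hour Urinary Sodium and
    Potassium Excretion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Develops and validates spot-urine estimating equations for
    24-hour urinary sodium and potassium excretion in stroke patients.
    Implements sex-specific linear estimating equations alongside the
    Kawasaki, INTERSALT and Tanaka formulas; urine-specimen quality-control
    filters; stepwise multiple linear regression for equation development on
    a random train/test split; and a full agreement-validation suite (mean
    bias with paired t-test, Pearson correlation with a dependent-correlations
    comparison, ICC(A,1) with F-based confidence intervals, P30 and
    relative/absolute cutoff proportions, Bland-Altman limits of agreement).
    A calibrated synthetic cohort generator reproduces the published marginal
    distributions and model-implied spot-to-24-hour correlation structure so
    the whole pipeline is testable without individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
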