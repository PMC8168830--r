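Package: misspipe
Title: Treatment and Reporting of Missing Data in Observational Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for handling and reporting missing data in
    observational studies. Simulates cohorts with controlled MCAR/MAR/MNAR
    missingness mechanisms, produces the standard missing-data diagnostics
    (per-variable missingness, complete versus incomplete comparison, a
    logistic model for predictors of completeness), encodes a deterministic
    flowchart for choosing between complete-records analysis and multiple
    imputation, runs fully-conditional-specification (chained equations)
    multiple imputation with Bayesian linear, Bayesian logistic and
    predictive-mean-matching column models, pools estimates by Rubin's rules
    with Barnard-Rubin degrees of freedom, performs pattern-mixture
    delta-offset sensitivity and tipping-point analyses, and emits
    reporting tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
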