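Package: sepsisalert
Title: Probabilistic Sepsis Alerting for Emergency Department Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating probabilistic sepsis screening
    alerts from first-hour emergency department data. Implements a Gaussian
    naive Bayes classifier that handles informatively missing laboratory
    values by omitting them from the likelihood, forward stepwise feature
    selection driven by bootstrap out-of-bag AUC, operating-point analytics
    for binary alerts (sensitivity, false positives per day, predictive
    values, threshold searches), monthly stability summaries based on the
    coefficient of variation, and a calibrated synthetic cohort generator so
    the full pipeline can be exercised without access to protected health
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
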