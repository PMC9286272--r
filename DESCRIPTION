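Package: hemaRI
Title: Nonparametric Reference Intervals for Hematological Parameters in
    Stratified Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Establishes complete-blood-count reference intervals for
    stratified cohorts (pregnancy trimesters and non-pregnant controls)
    following the CLSI/IFCC nonparametric framework: eligibility screening
    with participant-flow reporting, Dixon/Reed one-third-range outlier
    exclusion, rank-based 2.5th/97.5th percentile reference limits with
    distribution-free 90% confidence intervals (order-statistic or
    bootstrap), Mann-Whitney and Kruskal-Wallis partition comparisons, and
    out-of-range misclassification scoring against manufacturer intervals.
    Includes a quantile-calibrated synthetic cohort generator so the whole
    pipeline is testable without patient data.
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
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
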