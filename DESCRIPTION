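Package: uticdst
Title: Three-Question Decision Support for Urinary Tract Infection
    versus Asymptomatic Bacteriuria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a sequential three-question clinical decision-support
    rule that distinguishes urinary tract infection (UTI) from asymptomatic
    bacteriuria (ASB) in hospitalized adults, together with a retrospective
    validation pipeline: syndrome adjudication (ASB, cystitis, pyelonephritis,
    other infection), diagnostic accuracy with exact Clopper-Pearson confidence
    intervals, antibiotic days-of-therapy burden accounting stratified by
    appropriateness and agent class, and a synthetic electronic-health-record
    cohort generator including a deterministic 124-patient fixture cohort that
    satisfies the validation study's published marginal counts. Cohorts are
    tibbles; results carry tidy() and glance() methods and ggplot2 autoplot()
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
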