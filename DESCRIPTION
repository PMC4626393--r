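Package: cohortbump
Title: Detection of Local Birth-Cohort Effects in Age-Period Mortality Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a varying-coefficient Poisson model to age-period tabulated
    mortality (or incidence) counts in which the log rate is a polynomial
    interaction surface in age and period augmented by a Gaussian basis on the
    birth-cohort diagonal. A profile-deviance grid search over the center and
    width of the Gaussian cohort basis detects local birth-cohort effects
    automatically, Wald tests assess their significance, and the effect is
    reported as a relative-risk curve by birth year. Includes a simulator for
    synthetic age-period tables and a thin command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
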