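Package: avoidgap
Title: Decomposing Life Expectancy and Lifespan Inequality Gaps by
    Avoidable Causes of Death
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds abridged life tables from cause-of-death and population
    counts, computes life expectancy at birth and lifespan inequality (the
    standard deviation of the age-at-death distribution), and attributes
    cross-country gaps in both measures to age- and cause-specific mortality
    differences with a continuous-change (Horiuchi) decomposition. Causes of
    death are classified into five mutually exclusive avoidability groups
    (treatable, preventable, both, ischaemic heart disease, non-avoidable)
    under a configurable ICD-10 rule table with an upper age cap. Includes
    readers for a canonical long format and the WHO Mortality Database wide
    dialect, recalibration of cause-specific rates to external all-cause life
    tables for sensitivity analysis, and a seeded synthetic-data generator
    for two-country scenarios with known injected mortality differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
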