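Package: margpath
Title: Marginal-Effect Path Analysis of Obesity and Postoperative
    Outcomes in Administrative Claims Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how an exposure recorded in hospital
    discharge claims (obesity, ICD-9-CM 278.0) raises in-hospital
    mortality, length of stay, and total charges in surgical
    colorectal-cancer admissions through postoperative complications.
    Provides a synthetic generator of National-Inpatient-Sample-like
    admission records with a built-in exposure -> complication -> outcome
    causal structure, ICD-9-CM cohort extraction with attrition logging,
    1:4 exact case-control matching on age band, sex and metastasis,
    group descriptives (Pearson chi-square and two-sample t tests),
    multivariable logistic and ordinary-least-squares layers reporting
    publication-style statistics, and a path engine that converts
    log-odds coefficients into absolute marginal effects via
    b * P * (1 - P) and decomposes total indirect effects as sums of
    per-mediator products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
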