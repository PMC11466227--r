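Package: chcincidence
Title: Cumulative Incidence of Childhood Chronic Health Conditions from
    Linked Hospital and Education Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the cumulative incidence of chronic health
    conditions (CHCs) recorded in hospital inpatient data from birth to age 16.
    Implements ICD-10 phenotype ascertainment against a body-system grouped
    code list, closed birth-cohort eligibility (main plus seven sensitivity
    variants) with censoring at death, first non-England domicile record or
    the 16th birthday, one-minus-product-limit and Aalen-Johansen competing
    risk estimators, an open-cohort estimator using external mid-year
    population denominators discounted by cumulative cases, body-system
    multimorbidity summaries, linkage-rate tables, and a synthetic generator
    of linked hospital/education-style records with analytically known
    ground-truth hazards so every stage can be tested without access to
    restricted data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
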