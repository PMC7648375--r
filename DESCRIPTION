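Package: frids
Title: Medication-Related Fall Risk Categorization and Screening for Geriatric Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Categorizes medicines into high, moderate and no fall-risk
    classes (A/B/C) from the statutory frequency of balance-disturbing
    adverse effects in Summaries of Product Characteristics (SmPCs),
    profiles exposure to fall-risk-increasing drugs (FRIDs) at patient and
    cohort level, computes the routine 4-item admission fall-risk score and
    a medication-aware 5-item extension, and reproduces cohort-level
    descriptive tables (risk-category shares, ATC roll-ups, top-FRID
    rankings, score distributions). Ships a knowledge base of 102 high-risk
    substances with usage metadata from a 188-patient geriatric cohort and
    a seedable synthetic-cohort simulator calibrated to its marginals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
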