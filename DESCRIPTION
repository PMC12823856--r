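Package: pvsignal
Title: Disproportionality Signal Detection for Multi-Database Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes spontaneous adverse-event reports from three
    pharmacovigilance database dialects (FAERS-like, CVAR-like, JADER-like)
    into a common report model, constructs drug/event cohorts via
    primary-suspect restriction, indication filtering, standardized
    MedDRA-query event flagging and within/cross-database deduplication,
    and computes disproportionality statistics (proportional reporting
    ratio, reporting odds ratio, chi-square, Bayesian information component
    with IC025 shrinkage bound) per drug, per database and combined, with a
    three-criterion signal rule. Includes comparative analyses (fatality
    constituent ratios, pairwise Wald odds-ratio matrices, Fisher-exact
    volcano statistics, two-group proportional-odds severity comparison)
    and a synthetic multi-database report generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
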