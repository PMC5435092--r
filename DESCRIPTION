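Package: atopia
Title: Episode-Based Prevalence Estimation for Atopic Disorders in
    Primary Care EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate prevalences of childhood atopic disorders
    (atopic eczema, asthma, allergic rhinitis) from coded primary-care
    electronic health records.  Reconstructs ICPC-coded episodes of care
    under four case-definition strategies (recorded episodes,
    prescription-validated episodes, and their chronic extensions),
    applies practice-level data-quality and child-level eligibility
    filters with a full attrition account, computes per-age annual point
    prevalences and cumulative lifetime incidences, and derives
    co-occurrence (atopic triad), enrichment and remission statistics.
    Ships a seeded synthetic primary-care EHR generator for validation,
    calibration checks and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
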