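Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for FAERS-style quarterly report
    tables: ingestion of dollar-delimited DEMO/DRUG/REAC/OUTC/RPSR/THER/INDI
    files, case deduplication by latest submission date, primary-suspect
    cohort construction, per-PT 2x2 contingency tables against the
    full-database background, and four disproportionality statistics
    (reporting odds ratio, proportional reporting ratio with Pearson
    chi-square, the BCPNN information component, and the unshrunk empirical
    Bayes geometric mean) with interval bounds and threshold-based signal
    flags. Includes a seeded synthetic spontaneous-reporting generator with
    planted drug-event associations and known ground truth, so every pipeline
    stage is testable without access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
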