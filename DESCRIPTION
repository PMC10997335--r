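Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for FAERS-style spontaneous
    adverse-event report data: reading quarterly multi-table report files,
    MedDRA preferred-term to system-organ-class mapping, report deduplication
    and primary-suspect filtering, 2x2 contingency tables against the database
    background, and reporting odds ratio (ROR) / proportional reporting ratio
    (PRR) disproportionality statistics with dual-criteria signal calling.
    Includes descriptive summaries (demographics, serious outcomes, yearly
    counts, daily-dose analysis) and a synthetic-data generator with exact
    ground-truth manifests for validating every pipeline stage, built around
    the worked example of cardiac adverse events reported for the five
    triazole antifungal agents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
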