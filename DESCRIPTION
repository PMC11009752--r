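Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for pharmacovigilance disproportionality analysis of
    spontaneous adverse-event report databases in the style of the FDA
    Adverse Event Reporting System (FAERS): reading and deduplicating
    case versions, normalizing verbatim drug names to products and
    ingredients, grouping MedDRA-style preferred terms into outcome sets,
    estimating reporting odds ratios (ROR) with Wald confidence intervals
    and a lower-bound signal criterion, active-comparator and stratified
    designs, a configurable end-to-end study pipeline, and a synthetic
    report generator with known ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
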