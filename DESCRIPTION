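Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pharmacovigilance signal detection from individual case safety
    reports (ICSRs). Builds report-level drug by adverse-event 2x2 contingency
    tables, computes the proportional reporting ratio (PRR), reporting odds
    ratio (ROR) and the shrinkage information component (IC) of the BCPNN
    family with 95% intervals, and flags signals by the joint rule
    (n >= 3, PRR >= 2, ROR >= 2, IC interval lower bound >= 0). Includes a
    mock MedDRA-style hierarchy (PT/HLT/HLGT/SOC) for neurological filtering
    and rollups, age- and sex-stratified analysis, demographic summaries,
    treemap exports, a synthetic ICSR generator with planted associations of
    known strength, and a marginal-reconstruction utility that recovers a full
    2x2 table from a published report count, drug total, database total and
    printed PRR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
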