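Package: mwdeposit
Title: Transform Tagged Spreadsheets into Metabolomics Workbench Depositions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning messy tabular experiment metadata and measurement
    data into clean Metabolomics Workbench depositions. A pound-delimited tagging
    system extracts records from spreadsheet tables (CSV or multi-sheet XLSX) into
    a six-table experiment-description JSON representation (project, study,
    protocol, entity, measurement, factor) with entity-attribute-value field
    semantics. Layered validation covers the base schema, referential integrity,
    subject/sample lineage rules, protocol-dependent schemas compiled through
    parent-protocol inheritance chains, and mwTab conversion readiness. Declarative
    conversion directives then emit mwTab deposition files in both JSON and
    tab-delimited form for ms, nmr and nmr_binned analyses. A fixture generator
    fabricates a toy IC-FTMS-style study so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    readxl,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    zip
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
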