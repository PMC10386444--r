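# mwdeposit

Turn messy tabular experiment metadata and measurement data into clean
**Metabolomics Workbench** depositions.

Depositing a metabolomics dataset means transforming spreadsheets with ad
hoc layouts into the repository's mwTab format. `mwdeposit` implements a
three-command workflow for that transformation:

1. **extract** — a pound-delimited tagging system (`[*]#<table>.<field>[=literal]`
   tags placed in `#tags` rows above data tables) turns spreadsheet tables
   into a six-table experiment description: `project`, `study`, `protocol`,
   `entity`, `measurement`, `factor`. Records follow an
   entity–attribute–value pattern (`weight%unit` is the unit attribute of
   `weight`; `<table>.id` fields are cross-table references). Untagged
   tables can be tagged automatically by matching their headers
   (Levenshtein distance ≤ 2), and extracted records can be edited with
   prepend/append/delete/overwrite/regex-substitute directives.
2. **validate** — layered checks with stable finding codes: base schema
   (five protocol types: `treatment`, `collection`, `sample_prep`,
   `measurement`, `storage`; entities are `subject` or `sample`),
   referential integrity, lineage rules (a sample from a sample needs a
   sample_prep protocol; a sample from a subject needs a collection
   protocol; subjects should have a treatment protocol), factor-value
   constraints, protocol-dependent schemas compiled through
   `parent_protocol` inheritance chains, and mwTab conversion readiness.
3. **convert** — declarative conversion directives emit the deposition as
   mwTab JSON and tab-delimited text for `ms`, `nmr` or `nmr_binned`
   analyses, with `ANALYSIS_ID`/`STUDY_ID` defaulting to `000000` until the
   repository assigns real ids.

A fixture generator fabricates a toy IC-FTMS study (subjects → samples →
measurements) so the whole pipeline runs and tests offline.

## Worked example

```r
library(mwdeposit)

dir <- tempfile(); dir.create(dir)
paths <- generate_workbooks(fixture_params(), dir)   # metadata.xlsx, measurements.xlsx, CSVs
pds   <- generate_pds(file.path(dir, "pd_schema.csv"))

ds <- extract_dataset(c(paths[["metadata"]], paths[["measurements"]]))
ds
#> <mw_dataset>
#>   project      1 record(s)
#>   study        1 record(s)
#>   protocol     5 record(s)
#>   entity       6 record(s)
#>   factor       1 record(s)
#>   measurement  12 record(s)

validate_dataset(ds, pds = pds, format = "mwtab", silent = "nuisance")
#> <mw_validation_report> 0 error(s), 0 warning(s) [silent: nuisance]

doc <- build_mwtab(ds, "ms", created_on = "2023-07-12")
doc
#> <mwtab_document> ms: 8 section(s), 3 x 4 data matrix
#>   STUDY_ID 000000, ANALYSIS_ID 000000, CREATED_ON 2023-07-12
cat(substr(write_mwtab_txt(doc), 1, 95))
#> #METABOLOMICS WORKBENCH	STUDY_ID:000000	ANALYSIS_ID:000000	VERSION:1	CREATED_ON:2023-07-12
```

The six tables hold the full study description; validation reporting zero
findings at the `nuisance` silencing level means the dataset is deposition
ready; the built document's 3 × 4 matrix is the 3 metabolites × 4 samples
intensity block, and the `000000` ids are the placeholders a depositor
replaces (e.g. via a `--update` directive file) once Metabolomics Workbench
assigns real ones.

Or from the shell:

```sh
mwdeposit fixtures --out demo
mwdeposit extract demo/metadata.xlsx demo/measurements.xlsx --output demo/extracted.json
mwdeposit validate json demo/extracted.json --pds demo/pd_schema.csv --format mwtab --silent nuisance
mwdeposit convert mwtab ms demo/extracted.json demo/output   # writes output.json + output.txt
```

See `vignettes/deposition-workflow.Rmd` for the model, the tag grammar, the
validation severity rules and the normative mwTab mapping.

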