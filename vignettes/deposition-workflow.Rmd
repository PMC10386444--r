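---
title: "From tagged spreadsheets to mwTab depositions: the methods behind mwdeposit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tagged spreadsheets to mwTab depositions: the methods behind mwdeposit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwdeposit)
```

## The problem

Metabolomics and lipidomics datasets are deposited in public repositories
such as Metabolomics Workbench, which accepts the mwTab format (paired JSON
and tab-delimited representations). The data and metadata of a study,
however, usually start life scattered across spreadsheets with ad hoc
layouts. `mwdeposit` implements a three-stage transformation workflow —
**extract**, **validate**, **convert** — that turns such tabular sources into
a clean, validated mwTab deposition.

The intermediate representation is a six-table, entity–attribute–value (EAV)
store serialized as JSON: `project`, `study`, `protocol`, `entity`,
`measurement` and `factor`. Each table maps record ids to records; each
record is an open set of named text fields. Two conventions give the flat
EAV records structure:

* **Attribute fields.** A field `X%Y` is a descriptive attribute of field
  `X` in the same record — `weight%unit` holds the units of `weight`. An
  attribute without its base field is a validation error.
* **Reference fields.** A field named `<table>.id` holds one id (or a list
  of ids) referencing records of `<table>`; `parent_id` on entities
  references another entity. This is the only cross-table linking mechanism
  and it is machine-checkable.

Values are text-only throughout. Deposition formats are text, and a single
number-to-text rule (`render_number()`: integers bare, reals as the shortest
round-tripping decimal) avoids float drift between CSV, XLSX and JSON forms
of the same content.

## The tagging system

Extraction is driven by three kinds of directives that share one idea:
plain rows in a spreadsheet that describe how other rows should be read.

**Export tags** bind columns of a data table to (table, field) targets. The
grammar is `[*]#<table>.<field>[=<literal>]`. A block starts at a row whose
first cell is `#tags`; its remaining cells tag the columns below; data rows
run to the first blank row, the next `#tags` row, or `#end`. Exactly one tag
per block must bind the field `id` — it keys the records. A `*` prefix marks
a list field (cell split on commas, whitespace stripped; there is no escape
for literal commas — a documented limitation). An `=literal` suffix turns
the tag into a constant stamped into every record of the block.

**Automation directives** insert export tags into untagged tables by
matching their header row. Matching is exact first, then by Levenshtein
distance with a threshold of 2 — small enough that genuinely different
headers do not collide, large enough to absorb the one- and two-character
typos that dominate in practice. Ties at the minimal distance are reported
as errors rather than resolved arbitrarily. The tagged grid that automation
emits replaces the header row with the `#tags` row (and prepends a marker
column): the generic block scanner treats every row under the tag row as
data, so leaving the header row in place would turn the headers themselves
into a bogus record.

**Modification directives** edit records after extraction with a closed set
of five operations: `prepend`, `append`, `delete`, `overwrite` and
`regex-substitute`. Record selectors are exact ids unless they contain
regex metacharacters, in which case they are anchored full-match patterns.
One regular-expression dialect is used everywhere in the package — R's
default POSIX extended dialect with backreference-capable `gsub()`
replacement.

When several sources are merged, records union table-wise and field-wise;
on a genuine conflict the later source wins and a warning is emitted. This
later-wins policy keeps multi-source extraction associative and
predictable; order only matters where the inputs actually disagree.

## Validation layers

Every check emits findings from a fixed registry of stable codes, each an
error or a warning. The lineage rules translate must/should wording
directly into severities:

* a sample derived from a sample **must** have a `sample_prep` protocol
  (`LINEAGE_SAMPLEPREP_REQUIRED`, error);
* a sample derived from a subject **must** have a `collection` protocol
  (`LINEAGE_COLLECTION_REQUIRED`, error);
* subjects **should** have a `treatment` protocol
  (`LINEAGE_TREATMENT_RECOMMENDED`, warning).

The same generalization fixes the other severities: structural violations
(invalid protocol/entity types, id mismatches, orphaned attributes,
unresolved references, factor values outside their allowed set, missing
PD-schema requirements, missing mwTab prerequisites) are errors; advisory
matters are warnings. The *nuisance* subset — missing recommended
descriptive fields on project/study, unknown tables, unused factors,
protocols absent from the PD schema — is what `--silent nuisance` hides;
`--silent all` hides every warning; errors are never filtered, and the exit
status is nonzero exactly when an error survives filtering.

**Protocol-dependent schemas** add per-protocol requirements organized in a
`parent_protocol` inheritance table (JSON or tagged tabular form; in the
tabular form per-field allowed values use the attribute convention
`allowed_values%<field>`). Compilation walks each protocol's ancestry:
type is the protocol's own or the nearest ancestor's; required fields are
the union along the chain, ordered ancestor-first and alphabetically within
each level, so compiled output is deterministic; allowed values are
per-field with the child overriding the parent. Parent links must form a
forest — cycles and unresolvable types are hard errors at compile time.
A child's effective requirements are always a superset of its parent's,
and the test-suite property-checks this on random forests.

## Conversion to mwTab

Conversion is driven by declarative directives keyed by (section, key).
A directive is either string-valued — a literal, or a field lookup
(table, record selector, field, join delimiter) — or matrix-valued,
pivoting the measurement table into rows keyed by the metabolite
`assignment` and columns keyed by the referenced sample entity, both in
sorted order so output is deterministic. A missing cell becomes an empty
string with a warning; a duplicate (assignment, sample) pair is an error,
because silently picking one value would corrupt the deposition.

The built-in directive sets (one per machine type: `ms`, `nmr`,
`nmr_binned`) are the normative mapping for this package. The headline
defaults: `ANALYSIS_ID` and `STUDY_ID` are the literal `000000` until the
repository assigns real ids; `VERSION` is `1`; `CREATED_ON` is the current
date, injectable (`created_on =`) for reproducible output. Descriptive
sections pull `title`, `description`, `pi_first_name`, `pi_last_name`,
`institution`, `address`, `department` from project/study records;
COLLECTION/TREATMENT/SAMPLEPREP summaries join the descriptions of the
protocols of the corresponding type; the ANALYSIS and MS/NM sections read
instrument fields off the measurement-type protocol, with `-` placeholders
where optional metadata is absent. `--update` replaces individual
(section, key) entries and is idempotent; `--override` replaces whole
sections wholesale.

Factors rows in the data block render each sample's factor settings as
`name:value` pairs joined by `" | "`. A factor recorded on a subject applies
to its descendant samples: the renderer walks `parent_id` chains until it
finds the controlled field.

The tab-delimited dialect is documented in `R/mwtab_io.R`: a
`#METABOLOMICS WORKBENCH` first line with tab-separated `KEY:VALUE` tokens,
`#SECTION` banners with two-letter-prefixed lines (`PR:`, `ST:`, `SU:`,
`CO:`, `TR:`, `SP:`, `AN:`, `MS:`/`NM:`), data blocks bracketed by
`*_START`/`*_END` with `Samples` and `Factors` rows, a `METABOLITES` block
for `ms`/`nmr` (for `nmr_binned` the matrix row labels are the bin ranges
and no metabolite block is emitted), and a trailing `#END`.
`parse_mwtab_txt()` is the exact inverse on this dialect, which gives the
suite a round-trip contract tying the JSON and text outputs together.

## The fixture generator

All tests run against a fabricated desk-scale study: an ion chromatography
FTMS (IC-FTMS) targeted metabolomics experiment on mouse colon tissue.
Subjects (mice) carry a treatment protocol and a `time_point` factor with
levels 0 and 7 days; each subject contributes samples linked through
collection, sample-prep and storage protocols; each sample has one
intensity measurement per metabolite, produced by an untagged instrument
table that is tagged via automation and then corrected by a
regex-substitute modification renaming a legacy protocol id. Intensities
are log-normal (`exp(N(12, 1))`, rounded to one decimal) — a plausible
scale for FTMS peak areas; their distribution is irrelevant to what the
tests assert.

Defaults are 2 subjects × 2 samples × 3 metabolites (12 measurements,
26 records overall), and the property suites run on the order of 10³
randomized cases — sizes chosen so the whole suite exercises every code
path in seconds while keeping hand-enumerable expected counts. Workbooks
are written by a minimal deterministic XLSX writer (inline strings, pinned
archive timestamps), so identical parameters and seed give byte-identical
files, and CSV fallbacks of every sheet are emitted alongside.

What the fixtures deliberately do not emulate: realistic intensity
distributions and missingness, multi-study projects, formatted or merged
spreadsheet cells (grids are required to be plain and unmerged), and the
full breadth of a real deposition's metadata. Passing tests therefore
demonstrate the correctness of the transformation machinery, not that any
particular real-world spreadsheet will extract without manual tagging work.

Fault injection closes the loop: for every error code in the registry,
`generate_faulty()` mutates the clean fixture so that full validation
reports exactly that code and no other error code, and the suite asserts
this bijection.

## Design choices and limitations

* The core dataset container is a nested named list, not a data frame — it
  mirrors the JSON object-of-objects shape and EAV records have no fixed
  columns. `tidy()`/`glance()` methods provide the rectangular views.
* XLSX reading uses `readxl`; writing uses the package's own minimal
  ECMA-376 writer, which stores every cell as an inline string.
* CSV is RFC 4180 with comma delimiter; everything is UTF-8.
* `merge` conflicts, unmatched modification selectors and matrix gaps are
  warnings; structural violations are errors. Warnings never change exit
  status.
* Google Sheets sources, ODS, user-supplied code hooks in conversion
  directives, deeply nested output structures and deposition formats other
  than mwTab are out of scope.
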