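# Conversion directives: declarative instructions mapping the six-table
# representation onto mwTab sections.
#
# A directive produces either a string value (kind "str") or a data matrix
# (kind "matrix"). String sources are a literal, or a field lookup
# (table + record selector + field, multiple hits joined with a delimiter).
# Matrix sources name the table to pivot, the collate key (matrix row
# identity), the sample key (matrix columns) and the value field(s). The
# built-in sets below are the normative mapping for this implementation; use
# `update`/`override` in [load_directives()] to adjust them.

MACHINE_TYPES <- c("ms", "nmr", "nmr_binned")

MWTAB_HEADER_SECTION <- "METABOLOMICS WORKBENCH"

mwtab_section_order <- function(machine_type) {
  common <- c(
    MWTAB_HEADER_SECTION, "PROJECT", "STUDY", "SUBJECT",
    "COLLECTION", "TREATMENT", "SAMPLEPREP", "ANALYSIS"
  )
  switch(
    machine_type,
    ms = c(common, "MS", "MS_METABOLITE_DATA", "METABOLITES"),
    nmr = c(common, "NM", "NMR_METABOLITE_DATA", "METABOLITES"),
    nmr_binned = c(common, "NM", "NMR_BINNED_DATA"),
    mwd_abort(sprintf("unknown machine type '%s'", machine_type), "mwd_usage_error")
  )
}

data_block_name <- function(machine_type) {
  switch(machine_type,
    ms = "MS_METABOLITE_DATA",
    nmr = "NMR_METABOLITE_DATA",
    nmr_binned = "NMR_BINNED_DATA"
  )
}

src_literal <- function(value) list(type = "literal", value = value)

src_field <- function(table, field, selector = list(kind = "first"),
                      delimiter = "; ") {
  list(type = "field", table = table, field = field,
       selector = selector, delimiter = delimiter)
}

sel_first <- function() list(kind = "first")
sel_id <- function(id) list(kind = "id", id = id)
sel_field_eq <- function(field, value) list(kind = "field_eq", field = field, value = value)

src_matrix <- function(table = "measurement", collate_key = "assignment",
                       sample_key = "entity.id", value_fields = "intensity") {
  list(type = "matrix", table = table, collate_key = collate_key,
       sample_key = sample_key, value_fields = value_fields)
}

directive <- function(section, key, kind, source, required = FALSE, default = NA_character_) {
  list(section = section, key = key, kind = kind, source = source,
       required = required, default = default)
}

# Descriptive section shared by project and study.
contact_directives <- function(section, table) {
  list(
    directive(section, paste0(section, "_TITLE"), "str",
              src_field(table, "title"), required = TRUE),
    directive(section, paste0(section, "_SUMMARY"), "str",
              src_field(table, "description"), required = TRUE),
    directive(section, "INSTITUTE", "str", src_field(table, "institution"), required = TRUE),
    directive(section, "DEPARTMENT", "str", src_field(table, "department")),
    directive(section, "FIRST_NAME", "str", src_field(table, "pi_first_name"), required = TRUE),
    directive(section, "LAST_NAME", "str", src_field(table, "pi_last_name"), required = TRUE),
    directive(section, "ADDRESS", "str", src_field(table, "address")),
    directive(section, "EMAIL", "str", src_field(table, "pi_email"), default = "-")
  )
}

protocol_summary_directive <- function(section, type) {
  directive(
    section, paste0(section, "_SUMMARY"), "str",
    src_field("protocol", "description", sel_field_eq("type", type)),
    required = TRUE
  )
}

#' Built-in conversion directives
#'
#' The normative built-in mapping from the six-table representation to mwTab
#' sections for one machine type. `ANALYSIS_ID` and `STUDY_ID` default to
#' `"000000"`; `CREATED_ON` is injected at build time unless overridden.
#'
#' @param machine_type One of `ms`, `nmr`, `nmr_binned`.
#' @return A directive set (class `mw_directive_set`).
#' @export
builtin_directives <- function(machine_type = c("ms", "nmr", "nmr_binned")) {
  machine_type <- match.arg(machine_type)
  ds <- c(
    list(
      directive(MWTAB_HEADER_SECTION, "STUDY_ID", "str", src_literal("000000")),
      directive(MWTAB_HEADER_SECTION, "ANALYSIS_ID", "str", src_literal("000000")),
      directive(MWTAB_HEADER_SECTION, "VERSION", "str", src_literal("1")),
      directive(MWTAB_HEADER_SECTION, "CREATED_ON", "str", src_literal(NA_character_),
                default = "")
    ),
    contact_directives("PROJECT", "project"),
    contact_directives("STUDY", "study"),
    list(
      directive("SUBJECT", "SUBJECT_TYPE", "str",
                src_field("entity", "subject_type", sel_field_eq("type", "subject")),
                default = "-"),
      directive("SUBJECT", "SUBJECT_SPECIES", "str",
                src_field("entity", "species", sel_field_eq("type", "subject")),
                default = "-"),
      directive("SUBJECT", "TAXONOMY_ID", "str",
                src_field("entity", "taxonomy_id", sel_field_eq("type", "subject")),
                default = "-")
    ),
    list(
      protocol_summary_directive("COLLECTION", "collection"),
      protocol_summary_directive("TREATMENT", "treatment"),
      protocol_summary_directive("SAMPLEPREP", "sample_prep")
    ),
    list(
      directive("ANALYSIS", "ANALYSIS_TYPE", "str",
                src_literal(if (machine_type == "ms") "MS" else "NMR")),
      directive("ANALYSIS", "INSTRUMENT_NAME", "str",
                src_field("protocol", "instrument", sel_field_eq("type", "measurement")),
                default = "-"),
      directive("ANALYSIS", "ANALYSIS_PROTOCOL", "str",
                src_field("protocol", "description", sel_field_eq("type", "measurement")))
    )
  )
  ds <- c(ds, if (machine_type == "ms") {
    list(
      directive("MS", "INSTRUMENT_NAME", "str",
                src_field("protocol", "instrument", sel_field_eq("type", "measurement")),
                default = "-"),
      directive("MS", "INSTRUMENT_TYPE", "str",
                src_field("protocol", "instrument_type", sel_field_eq("type", "measurement")),
                default = "-"),
      directive("MS", "MS_TYPE", "str",
                src_field("protocol", "ms_type", sel_field_eq("type", "measurement")),
                default = "-"),
      directive("MS", "ION_MODE", "str",
                src_field("protocol", "ion_mode", sel_field_eq("type", "measurement")),
                default = "-"),
      directive("MS", "CHROMATOGRAPHY_TYPE", "str",
                src_field("protocol", "chromatography_type", sel_field_eq("type", "measurement")),
                default = "-")
    )
  } else {
    list(
      directive("NM", "INSTRUMENT_NAME", "str",
                src_field("protocol", "instrument", sel_field_eq("type", "measurement")),
                default = "-"),
      directive("NM", "INSTRUMENT_TYPE", "str",
                src_field("protocol", "instrument_type", sel_field_eq("type", "measurement")),
                default = "-"),
      directive("NM", "NMR_EXPERIMENT_TYPE", "str",
                src_field("protocol", "nmr_experiment_type", sel_field_eq("type", "measurement")),
                default = "-")
    )
  })
  dblock <- data_block_name(machine_type)
  ds <- c(ds, list(
    directive(dblock, "UNITS", "str",
              src_field("measurement", "intensity%type"), default = "intensity"),
    directive(dblock, "Data", "matrix", src_matrix(), required = TRUE)
  ))
  if (machine_type %in% c("ms", "nmr")) {
    ds <- c(ds, list(
      directive("METABOLITES", "Data", "matrix",
                src_matrix(value_fields = "formula"), required = TRUE)
    ))
  }
  structure(
    list(machine_type = machine_type, directives = ds),
    class = "mw_directive_set"
  )
}

validate_directive <- function(d, locus) {
  ok_keys <- c("section", "key", "kind", "source", "required", "default")
  if (!is.list(d) || is.null(d$section) || is.null(d$key) || is.null(d$kind) ||
      is.null(d$source)) {
    mwd_abort(
      sprintf("%s: a directive needs section, key, kind and source", locus),
      "mwd_directive_error"
    )
  }
  if (length(setdiff(names(d), ok_keys)) > 0L) {
    mwd_abort(
      sprintf("%s: unknown directive member(s): %s", locus,
              paste(setdiff(names(d), ok_keys), collapse = ", ")),
      "mwd_directive_error"
    )
  }
  if (!d$kind %in% c("str", "matrix")) {
    mwd_abort(sprintf("%s: kind must be 'str' or 'matrix'", locus), "mwd_directive_error")
  }
  st <- d$source$type %||% ""
  if (!st %in% c("literal", "field", "matrix")) {
    mwd_abort(sprintf("%s: source type must be literal, field or matrix", locus),
              "mwd_directive_error")
  }
  if (d$kind == "matrix") {
    if (st != "matrix") {
      mwd_abort(sprintf("%s: matrix directives need a matrix source", locus),
                "mwd_directive_error")
    }
    if (!grepl("_DATA$|^METABOLITES$", d$section)) {
      mwd_abort(
        sprintf("%s: matrix directives are only allowed in data/metabolite sections", locus),
        "mwd_directive_error"
      )
    }
  }
  invisible(d)
}

normalize_json_directive <- function(section, key, raw, locus) {
  src <- raw$source
  if (!is.null(src)) {
    src <- lapply(src, function(v) if (is.list(v)) lapply(v, unlist) else unlist(v))
    if (!is.null(src$value_fields)) src$value_fields <- unlist(raw$source$value_fields)
    if (identical(src$type, "field")) {
      src$selector <- src$selector %||% sel_first()
      src$delimiter <- src$delimiter %||% "; "
    }
  }
  d <- directive(
    section, key,
    kind = raw$kind %||% "str",
    source = src,
    required = isTRUE(raw$required),
    default = raw$default %||% NA_character_
  )
  validate_directive(d, locus)
}

read_directive_file <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  assert_named_object(raw, path)
  out <- list()
  for (section in names(raw)) {
    assert_named_object(raw[[section]], sprintf("%s section '%s'", path, section))
    for (key in names(raw[[section]])) {
      out[[length(out) + 1L]] <- normalize_json_directive(
        section, key, raw[[section]][[key]],
        sprintf("%s %s/%s", path, section, key)
      )
    }
  }
  out
}

dset_index <- function(dirs) {
  vapply(dirs, function(d) paste0(d$section, "\r", d$key), character(1))
}

#' Load conversion directives
#'
#' Starts from the built-ins for `machine_type`. `update` deep-merges user
#' entries over the built-ins, replacing only the (section, key) pairs the
#' file mentions. `override` discards all built-ins for every section the
#' file mentions and uses the file's entries for those sections alone. Both
#' files are structure-validated before use.
#'
#' @param machine_type One of `ms`, `nmr`, `nmr_binned`.
#' @param update,override Optional paths to directive JSON files.
#' @return A directive set (class `mw_directive_set`).
#' @export
load_directives <- function(machine_type, update = NULL, override = NULL) {
  if (!machine_type %in% MACHINE_TYPES) {
    mwd_abort(
      sprintf("unknown machine type '%s' (must be one of %s)",
              machine_type, paste(MACHINE_TYPES, collapse = ", ")),
      "mwd_usage_error"
    )
  }
  dset <- builtin_directives(machine_type)
  if (!is.null(override)) {
    user <- read_directive_file(override)
    drop <- unique(vapply(user, function(d) d$section, character(1)))
    dset$directives <- c(
      Filter(function(d) !d$section %in% drop, dset$directives),
      user
    )
  }
  if (!is.null(update)) {
    user <- read_directive_file(update)
    idx <- dset_index(dset$directives)
    for (d in user) {
      at <- match(paste0(d$section, "\r", d$key), idx)
      if (is.na(at)) {
        dset$directives[[length(dset$directives) + 1L]] <- d
        idx <- c(idx, paste0(d$section, "\r", d$key))
      } else {
        dset$directives[[at]] <- utils::modifyList(dset$directives[[at]], d)
      }
    }
  }
  order <- mwtab_section_order(machine_type)
  secs <- vapply(dset$directives, function(d) d$section, character(1))
  dset$directives <- dset$directives[order(match(secs, order, nomatch = length(order) + 1L))]
  dset
}
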