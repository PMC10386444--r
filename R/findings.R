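# Findings and validation reports.
#
# Every check emits findings from a fixed registry of stable codes, so
# downstream tooling (and the test-suite) can assert on codes rather than
# message text. "Nuisance" marks the common warnings most users silence.

FINDING_REGISTRY <- tibble::tribble(
  ~code,                          ~severity,  ~nuisance,
  "PROTOCOL_TYPE_INVALID",        "error",    FALSE,
  "ENTITY_TYPE_INVALID",          "error",    FALSE,
  "ID_MISMATCH",                  "error",    FALSE,
  "ID_MISSING",                   "error",    FALSE,
  "ATTRIBUTE_ORPHANED",           "error",    FALSE,
  "REF_UNRESOLVED",               "error",    FALSE,
  "LINEAGE_SAMPLEPREP_REQUIRED",  "error",    FALSE,
  "LINEAGE_COLLECTION_REQUIRED",  "error",    FALSE,
  "FACTOR_VALUE_INVALID",         "error",    FALSE,
  "PDS_FIELD_MISSING",            "error",    FALSE,
  "PDS_TYPE_MISMATCH",            "error",    FALSE,
  "PDS_VALUE_INVALID",            "error",    FALSE,
  "MWTAB_MISSING_PROTOCOL",       "error",    FALSE,
  "MWTAB_MISSING_FIELD",          "error",    FALSE,
  "MWTAB_MISSING_RECORD",         "error",    FALSE,
  "LINEAGE_TREATMENT_RECOMMENDED","warning",  FALSE,
  "TABLE_UNKNOWN",                "warning",  TRUE,
  "FIELD_RECOMMENDED_MISSING",    "warning",  TRUE,
  "FACTOR_UNUSED",                "warning",  TRUE,
  "PDS_UNKNOWN_PROTOCOL",         "warning",  TRUE
)

#' The finding-code registry
#'
#' @return A tibble with columns `code`, `severity` and `nuisance` listing
#'   every finding the validators can emit.
#' @export
finding_codes <- function() FINDING_REGISTRY

empty_findings <- function() {
  tibble::tibble(
    severity = character(), code = character(), table = character(),
    record = character(), field = character(), message = character(),
    nuisance = logical()
  )
}

# One finding row; severity and nuisance flag come from the registry.
finding <- function(code, message, table = NA_character_, record = NA_character_,
                    field = NA_character_) {
  reg <- FINDING_REGISTRY[FINDING_REGISTRY$code == code, ]
  if (nrow(reg) != 1L) {
    mwd_abort(sprintf("unregistered finding code '%s'", code), "mwd_internal_error")
  }
  tibble::tibble(
    severity = reg$severity, code = code, table = table, record = record,
    field = field, message = message, nuisance = reg$nuisance
  )
}

bind_findings <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) !is.null(p) && nrow(p) > 0L, logical(1))]
  if (length(parts) == 0L) return(empty_findings())
  dplyr::bind_rows(parts)
}

#' Filter findings into a validation report
#'
#' `silent = "none"` keeps everything; `"nuisance"` drops findings flagged as
#' nuisance; `"all"` drops every warning. Errors are never filtered.
#'
#' @param findings A findings tibble (as returned by the validators).
#' @param silent One of `"none"`, `"nuisance"`, `"all"`.
#' @return An object of class `mw_validation_report`.
#' @export
filter_findings <- function(findings, silent = c("none", "nuisance", "all")) {
  silent <- match.arg(silent)
  kept <- switch(
    silent,
    none = findings,
    nuisance = findings[findings$severity == "error" | !findings$nuisance, , drop = FALSE],
    all = findings[findings$severity == "error", , drop = FALSE]
  )
  structure(
    list(
      findings = tibble::as_tibble(kept),
      n_errors = sum(kept$severity == "error"),
      n_warnings = sum(kept$severity == "warning"),
      silent = silent
    ),
    class = "mw_validation_report"
  )
}

#' @export
print.mw_validation_report <- function(x, ...) {
  cat(sprintf(
    "<mw_validation_report> %d error(s), %d warning(s) [silent: %s]\n",
    x$n_errors, x$n_warnings, x$silent
  ))
  if (nrow(x$findings) > 0L) {
    for (i in seq_len(nrow(x$findings))) {
      f <- x$findings[i, ]
      locus <- paste(stats::na.omit(c(f$table, f$record, f$field)), collapse = "/")
      cat(sprintf(
        "  %-7s %-28s %s%s\n", f$severity, f$code,
        if (nzchar(locus)) paste0(locus, ": ") else "", f$message
      ))
    }
  }
  invisible(x)
}

#' @rdname filter_findings
#' @param x An `mw_validation_report`.
#' @param ... Unused.
#' @export
tidy.mw_validation_report <- function(x, ...) x$findings

#' @rdname filter_findings
#' @export
glance.mw_validation_report <- function(x, ...) {
  tibble::tibble(
    n_findings = nrow(x$findings),
    n_errors = x$n_errors,
    n_warnings = x$n_warnings,
    n_nuisance = sum(x$findings$nuisance),
    silent = x$silent
  )
}

#' Plot a validation report
#'
#' Bar chart of finding counts by code, filled by severity.
#'
#' @param object An `mw_validation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mw_validation_report <- function(object, ...) {
  df <- object$findings
  if (nrow(df) == 0L) {
    df <- tibble::tibble(code = "none", severity = "ok", n = 0L)
  } else {
    df <- dplyr::count(df, .data$code, .data$severity, name = "n")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$code, y = .data$n, fill = .data$severity)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "findings", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize a report to JSON
#'
#' @param report An `mw_validation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(
      n_errors = report$n_errors,
      n_warnings = report$n_warnings,
      silent = report$silent,
      findings = report$findings
    ),
    path, auto_unbox = TRUE, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
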