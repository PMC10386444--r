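# Modification directives: post-extraction record edits.
#
# Five operations form a closed set: prepend, append, delete, overwrite,
# regex-substitute. Record selectors are exact ids unless they contain regex
# metacharacters, in which case they are anchored full-match patterns. The
# regular-expression dialect everywhere in the package is R's default POSIX
# extended dialect with backreference-capable replacement (gsub()).

MOD_OPERATIONS <- c("prepend", "append", "delete", "overwrite", "regex-substitute")

#' Build a modification directive
#'
#' @param table Target table name.
#' @param records Record selector: exact id, or anchored full-match pattern if
#'   it contains regex metacharacters.
#' @param field Field to edit.
#' @param operation One of prepend, append, delete, overwrite,
#'   regex-substitute.
#' @param value Text to prepend/append/overwrite with; for regex-substitute,
#'   the replacement (backreferences allowed).
#' @param pattern Pattern for regex-substitute (unused otherwise).
#' @return A list of class `mw_modification_directive`.
#' @export
modification_directive <- function(table, records, field, operation,
                                   value = "", pattern = NA_character_) {
  if (!operation %in% MOD_OPERATIONS) {
    mwd_abort(
      sprintf("unknown modification operation '%s' (must be one of %s)",
              operation, paste(MOD_OPERATIONS, collapse = ", ")),
      "mwd_directive_error"
    )
  }
  if (operation == "regex-substitute" && (is.na(pattern) || !nzchar(pattern))) {
    mwd_abort("regex-substitute needs a pattern", "mwd_directive_error")
  }
  structure(
    list(table = table, records = records, field = field,
         operation = operation, value = value, pattern = pattern),
    class = "mw_modification_directive"
  )
}

#' Build a delete selector
#'
#' @param table Table to delete records from.
#' @param pattern Exact id or anchored full-match pattern.
#' @return A list of class `mw_delete_selector`.
#' @export
delete_selector <- function(table, pattern) {
  if (!nzchar(table)) mwd_abort("delete selector needs a table", "mwd_directive_error")
  structure(list(table = table, pattern = pattern), class = "mw_delete_selector")
}

has_regex_meta <- function(x) grepl("[][\\^$.|?*+(){}]", x)

# ids matching an exact-or-anchored-pattern selector
selector_matches <- function(ids, selector, locus = "selector") {
  if (length(ids) == 0L) return(character(0))
  if (!has_regex_meta(selector)) return(ids[ids == selector])
  res <- tryCatch(
    grepl(paste0("^(", selector, ")$"), ids),
    error = function(e) {
      mwd_abort(sprintf("%s: invalid pattern '%s'", locus, selector),
                "mwd_pattern_error")
    },
    warning = function(w) {
      mwd_abort(sprintf("%s: invalid pattern '%s'", locus, selector),
                "mwd_pattern_error")
    }
  )
  ids[res]
}

parse_modification_grid <- function(grid) {
  cells <- grid$cells
  hdr_row <- which(apply(cells, 1L, function(r) any(nzchar(trimws(r)))))[1]
  if (is.na(hdr_row)) return(list())
  headers <- tolower(trimws(cells[hdr_row, ]))
  need <- c("table", "records", "field", "operation")
  cols <- match(c(need, "value", "pattern"), headers)
  names(cols) <- c(need, "value", "pattern")
  if (any(is.na(cols[need]))) {
    mwd_abort(
      sprintf("%s: modification table needs columns %s",
              grid_locus(grid, hdr_row), paste(need, collapse = ", ")),
      "mwd_directive_error"
    )
  }
  cell_or <- function(i, col, default) {
    if (is.na(col)) default else trimws(cells[i, col])
  }
  out <- list()
  for (i in seq_len(nrow(cells))) {
    if (i <= hdr_row) next
    if (all(!nzchar(trimws(cells[i, ])))) next
    pat <- cell_or(i, cols[["pattern"]], "")
    out[[length(out) + 1L]] <- modification_directive(
      table = trimws(cells[i, cols[["table"]]]),
      records = trimws(cells[i, cols[["records"]]]),
      field = trimws(cells[i, cols[["field"]]]),
      operation = trimws(cells[i, cols[["operation"]]]),
      value = cell_or(i, cols[["value"]], ""),
      pattern = if (nzchar(pat)) pat else NA_character_
    )
  }
  out
}

parse_modification_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(d) {
    modification_directive(
      d$table %||% mwd_abort("modification directive without 'table'", "mwd_directive_error"),
      d$records %||% mwd_abort("modification directive without 'records'", "mwd_directive_error"),
      d$field %||% mwd_abort("modification directive without 'field'", "mwd_directive_error"),
      d$operation %||% mwd_abort("modification directive without 'operation'", "mwd_directive_error"),
      value = d$value %||% "",
      pattern = d$pattern %||% NA_character_
    )
  })
}

#' Read modification directives from a file
#'
#' Accepts a JSON array of directive objects or a tabular source (default
#' XLSX sheet `#modify`) with columns table, records, field, operation,
#' value, pattern.
#'
#' @param spec A path, `"path:sheet"` string, or parsed source spec.
#' @return List of [modification_directive()]s.
#' @export
read_modification_directives <- function(spec) {
  if (is.character(spec)) spec <- parse_source_spec(spec)
  if (grepl("\\.json$", spec$path, ignore.case = TRUE)) {
    return(parse_modification_json(spec$path))
  }
  sheet <- if (is_xlsx(spec$path) && is.na(spec$sheet)) "#modify" else spec$sheet
  parse_modification_grid(read_grid(list(path = spec$path, sheet = sheet)))
}

apply_one_mod <- function(value, d, locus) {
  vals <- field_values(value)
  listish <- is_list_field(value)
  out <- switch(
    d$operation,
    "prepend" = paste0(d$value, vals),
    "append" = paste0(vals, d$value),
    "overwrite" = d$value,
    "regex-substitute" = tryCatch(
      gsub(d$pattern, d$value, vals),
      error = function(e) {
        mwd_abort(sprintf("%s: invalid pattern '%s'", locus, d$pattern),
                  "mwd_pattern_error")
      },
      warning = function(w) {
        mwd_abort(sprintf("%s: invalid pattern '%s'", locus, d$pattern),
                  "mwd_pattern_error")
      }
    ),
    mwd_abort(sprintf("unhandled operation '%s'", d$operation), "mwd_directive_error")
  )
  if (listish && d$operation != "overwrite") I(out) else out
}

#' Apply modification directives to a dataset
#'
#' Directives are applied in listed order to every record of the named table
#' whose id matches the directive's selector. prepend/append concatenate text
#' (element-wise for list fields); delete removes the field; overwrite
#' replaces the value; regex-substitute rewrites every element. A directive
#' matching zero records emits a warning, not an error.
#'
#' @param dataset An [mw_dataset()].
#' @param mods List of [modification_directive()]s.
#' @return The modified dataset.
#' @export
apply_modifications <- function(dataset, mods) {
  for (k in seq_along(mods)) {
    d <- mods[[k]]
    locus <- sprintf("modification directive %d", k)
    ids <- selector_matches(names(ds_table(dataset, d$table)), d$records, locus)
    touched <- 0L
    for (id in ids) {
      rec <- dataset$tables[[d$table]][[id]]
      if (!d$field %in% names(rec)) next
      touched <- touched + 1L
      if (d$operation == "delete") {
        rec[[d$field]] <- NULL
      } else {
        rec[[d$field]] <- apply_one_mod(rec[[d$field]], d, locus)
      }
      dataset$tables[[d$table]][[id]] <- rec
    }
    if (touched == 0L) {
      mwd_warn(
        sprintf("%s (%s/%s/%s) matched no records", locus, d$table, d$records, d$field),
        "mwd_no_match_warning"
      )
    }
  }
  dataset
}

#' Delete records from a dataset
#'
#' Matching records are removed. Dangling references left behind are reported
#' by validation, not here. A selector naming an unknown table warns and is
#' skipped.
#'
#' @param dataset An [mw_dataset()].
#' @param selectors List of [delete_selector()]s.
#' @return The dataset without the matched records.
#' @export
delete_entries <- function(dataset, selectors) {
  for (sel in selectors) {
    if (!sel$table %in% names(dataset$tables)) {
      mwd_warn(sprintf("delete selector targets unknown table '%s'", sel$table),
               "mwd_unknown_table_warning")
      next
    }
    ids <- selector_matches(names(dataset$tables[[sel$table]]), sel$pattern,
                            sprintf("delete selector %s", sel$table))
    if (length(ids) == 0L) {
      mwd_warn(
        sprintf("delete selector %s=%s matched no records", sel$table, sel$pattern),
        "mwd_no_match_warning"
      )
      next
    }
    dataset$tables[[sel$table]] <- dataset$tables[[sel$table]][
      setdiff(names(dataset$tables[[sel$table]]), ids)
    ]
  }
  dataset
}
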