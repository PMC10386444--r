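# Building mwTab documents from a validated dataset.

SECTION_PREFIXES <- c(
  PROJECT = "PR", STUDY = "ST", SUBJECT = "SU", COLLECTION = "CO",
  TREATMENT = "TR", SAMPLEPREP = "SP", ANALYSIS = "AN", MS = "MS", NM = "NM"
)

select_records <- function(dataset, table, selector) {
  recs <- ds_table(dataset, table)
  if (length(recs) == 0L) return(recs)
  switch(
    selector$kind %||% "first",
    first = recs[1],
    id = recs[intersect(selector$id, names(recs))],
    field_eq = Filter(
      function(r) {
        !is.null(r[[selector$field]]) &&
          selector$value %in% field_values(r[[selector$field]])
      },
      recs
    ),
    all = recs,
    mwd_abort(sprintf("unknown selector kind '%s'", selector$kind), "mwd_directive_error")
  )
}

#' Evaluate a string-valued conversion directive
#'
#' Literals return their text. Field sources locate records through the
#' directive's selector, read the field, and join multiple values with the
#' delimiter. An absent value falls back to the directive's default; with no
#' default, a required directive raises a `CONVERSION_MISSING` error and an
#' optional one warns and returns `""`.
#'
#' @param d A directive (kind `"str"`).
#' @param dataset An [mw_dataset()].
#' @return A single string.
#' @export
evaluate_str_directive <- function(d, dataset) {
  stopifnot(identical(d$kind, "str"))
  locus <- sprintf("%s/%s", d$section, d$key)
  value <- NULL
  if (d$source$type == "literal") {
    value <- d$source$value
    if (!is.null(value) && is.na(value)) value <- NULL
  } else if (d$source$type == "field") {
    recs <- select_records(dataset, d$source$table, d$source$selector)
    vals <- character(0)
    for (r in recs) {
      if (!is.null(r[[d$source$field]])) {
        vals <- c(vals, field_values(r[[d$source$field]]))
      }
    }
    vals <- unique(vals[nzchar(vals)])
    if (length(vals) > 0L) value <- paste(vals, collapse = d$source$delimiter %||% "; ")
  } else {
    mwd_abort(sprintf("%s: source type '%s' is not string-valued", locus, d$source$type),
              "mwd_directive_error")
  }
  if (is.null(value) || !nzchar(value)) {
    if (!is.na(d$default)) return(d$default)
    if (isTRUE(d$required)) {
      mwd_abort(sprintf("%s: required directive resolved to nothing", locus),
                "mwd_conversion_missing_error")
    }
    mwd_warn(sprintf("%s: directive resolved to nothing; emitting empty value", locus),
             "mwd_conversion_empty_warning")
    return("")
  }
  value
}

#' Evaluate a matrix-valued conversion directive
#'
#' Collects the records of the source table, groups them by the collate key
#' (e.g. the metabolite assignment), and pivots per-sample values into a
#' matrix whose columns are the sample ids in sorted order and whose rows are
#' the collate values in sorted order. A missing (collate, sample) cell
#' becomes `""` with a warning; a duplicate pair is an error.
#'
#' @param d A directive (kind `"matrix"`).
#' @param dataset An [mw_dataset()].
#' @return A list with `samples` (column ids) and `rows` (a tibble: first
#'   column `row_name`, then one column per sample for single-value-field
#'   matrices, or one column per value field for attribute matrices).
#' @export
evaluate_matrix_directive <- function(d, dataset) {
  stopifnot(identical(d$kind, "matrix"))
  src <- d$source
  locus <- sprintf("%s/%s", d$section, d$key)
  recs <- ds_table(dataset, src$table)
  if (length(recs) == 0L) {
    if (isTRUE(d$required)) {
      mwd_abort(sprintf("%s: no '%s' records to build the matrix from", locus, src$table),
                "mwd_conversion_missing_error")
    }
    return(list(samples = character(0), rows = tibble::tibble(row_name = character(0))))
  }
  get1 <- function(r, f) {
    if (is.null(r[[f]])) NA_character_ else field_values(r[[f]])[1]
  }
  keys <- vapply(recs, get1, character(1), f = src$collate_key)
  if (anyNA(keys)) {
    mwd_abort(
      sprintf("%s: %d record(s) lack the collate field '%s'",
              locus, sum(is.na(keys)), src$collate_key),
      "mwd_conversion_missing_error"
    )
  }
  if (d$section == "METABOLITES") {
    # attribute matrix (e.g. METABOLITES): one row per collate value, one
    # column per value field, first record per group wins
    row_names <- sort(unique(unname(keys)))
    cols <- lapply(src$value_fields, function(f) {
      vapply(row_names, function(k) {
        r <- recs[[which(keys == k)[1]]]
        v <- get1(r, f)
        if (is.na(v)) "" else v
      }, character(1), USE.NAMES = FALSE)
    })
    names(cols) <- src$value_fields
    rows <- tibble::tibble(row_name = row_names, !!!cols)
    return(list(samples = character(0), rows = rows))
  }
  samples <- vapply(recs, get1, character(1), f = src$sample_key)
  if (anyNA(samples)) {
    mwd_abort(
      sprintf("%s: %d record(s) lack the sample field '%s'",
              locus, sum(is.na(samples)), src$sample_key),
      "mwd_conversion_missing_error"
    )
  }
  sample_ids <- sort(unique(unname(samples)))
  row_names <- sort(unique(unname(keys)))
  cells <- matrix("", nrow = length(row_names), ncol = length(sample_ids),
                  dimnames = list(row_names, sample_ids))
  filled <- matrix(FALSE, nrow = length(row_names), ncol = length(sample_ids),
                   dimnames = list(row_names, sample_ids))
  vf <- src$value_fields[1]
  for (i in seq_along(recs)) {
    k <- keys[i]; s <- samples[i]
    if (filled[k, s]) {
      mwd_abort(
        sprintf("%s: duplicate cell for (%s, %s)", locus, k, s),
        "mwd_ambiguous_cell_error"
      )
    }
    v <- get1(recs[[i]], vf)
    cells[k, s] <- if (is.na(v)) "" else v
    filled[k, s] <- TRUE
  }
  if (!all(filled)) {
    mwd_warn(
      sprintf("%s: %d empty cell(s) in the data matrix", locus, sum(!filled)),
      "mwd_matrix_gap_warning"
    )
  }
  rows <- tibble::tibble(row_name = row_names)
  for (s in sample_ids) rows[[s]] <- unname(cells[, s])
  list(samples = sample_ids, rows = rows)
}

# "name:value | name:value" factor string for one sample entity.
render_factors <- function(dataset, sample_id) {
  facs <- ds_table(dataset, "factor")
  ent <- ds_record(dataset, "entity", sample_id)
  pairs <- character(0)
  for (fid in names(facs)) {
    fname <- facs[[fid]]$field
    if (is.null(fname)) next
    fname <- field_values(fname)[1]
    holder <- ent
    # factors recorded on the subject apply to its descendant samples
    while (!is.null(holder) && !fname %in% names(holder)) {
      pid <- holder$parent_id
      holder <- if (is.null(pid)) NULL else ds_record(dataset, "entity", field_values(pid)[1])
    }
    if (!is.null(holder)) {
      pairs <- c(pairs, paste0(fname, ":", field_values(holder[[fname]])[1]))
    }
  }
  paste(pairs, collapse = " | ")
}

#' Build an mwTab document
#'
#' Evaluates every directive of the set in mwTab section order and assembles
#' the deposition document: the METABOLOMICS WORKBENCH header (ANALYSIS_ID
#' and STUDY_ID default to `000000`), the descriptive sections, the data
#' matrix with its Samples and Factors rows, and the METABOLITES block for
#' ms/nmr. Unless `force = TRUE`, the dataset must first pass the mwTab
#' readiness checks.
#'
#' @param dataset An [mw_dataset()].
#' @param machine_type One of `ms`, `nmr`, `nmr_binned`.
#' @param directives A directive set; defaults to [load_directives()] on
#'   `machine_type`.
#' @param created_on `CREATED_ON` value; defaults to today's date (ISO 8601).
#'   Inject a fixed date for reproducible output.
#' @param force Skip the readiness gate.
#' @return An object of class `mwtab_document`.
#' @export
build_mwtab <- function(dataset, machine_type = c("ms", "nmr", "nmr_binned"),
                        directives = NULL, created_on = NULL, force = FALSE) {
  machine_type <- match.arg(machine_type)
  if (is.null(directives)) directives <- load_directives(machine_type)
  if (!force) {
    gate <- validate_format_mwtab(dataset, machine_type)
    errs <- gate[gate$severity == "error", , drop = FALSE]
    if (nrow(errs) > 0L) {
      mwd_abort(
        paste0(
          "dataset is not mwTab-ready (use force = TRUE to try anyway):\n",
          paste0("  ", errs$code, ": ", errs$message, collapse = "\n")
        ),
        "mwd_conversion_gate_error"
      )
    }
  }
  dblock <- data_block_name(machine_type)
  header <- c(
    STUDY_ID = "000000", ANALYSIS_ID = "000000", VERSION = "1",
    CREATED_ON = created_on %||% format(Sys.Date())
  )
  sections <- list()
  data <- list(name = dblock, units = "", samples = character(0),
               factors = character(0), rows = tibble::tibble(row_name = character(0)))
  metabolites <- NULL
  for (d in directives$directives) {
    if (d$kind == "matrix") {
      m <- evaluate_matrix_directive(d, dataset)
      if (d$section == dblock) {
        data$samples <- m$samples
        data$rows <- m$rows
      } else {
        metabolites <- m$rows
      }
      next
    }
    value <- evaluate_str_directive(d, dataset)
    if (d$section == MWTAB_HEADER_SECTION) {
      if (d$key == "CREATED_ON" && !nzchar(value)) {
        value <- created_on %||% format(Sys.Date())
      }
      header[[d$key]] <- value
    } else if (d$section == dblock) {
      if (d$key == "UNITS") data$units <- value
    } else {
      if (is.null(sections[[d$section]])) sections[[d$section]] <- character(0)
      sections[[d$section]][[d$key]] <- value
    }
  }
  data$factors <- vapply(data$samples, function(s) render_factors(dataset, s), character(1),
                         USE.NAMES = FALSE)
  structure(
    list(machine_type = machine_type, header = header,
         sections = sections, data = data, metabolites = metabolites),
    class = "mwtab_document"
  )
}

#' @export
print.mwtab_document <- function(x, ...) {
  cat(sprintf(
    "<mwtab_document> %s: %d section(s), %d x %d data matrix\n",
    x$machine_type, length(x$sections),
    nrow(x$data$rows), length(x$data$samples)
  ))
  cat(sprintf("  STUDY_ID %s, ANALYSIS_ID %s, CREATED_ON %s\n",
              x$header[["STUDY_ID"]], x$header[["ANALYSIS_ID"]],
              x$header[["CREATED_ON"]]))
  invisible(x)
}

#' Tidy an mwTab document
#'
#' @param x An `mwtab_document`.
#' @param ... Unused.
#' @return A tibble with columns section, key, value covering the header and
#'   every descriptive section.
#' @export
tidy.mwtab_document <- function(x, ...) {
  rows <- list(tibble::tibble(
    section = MWTAB_HEADER_SECTION, key = names(x$header),
    value = unname(x$header)
  ))
  for (s in names(x$sections)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      section = s, key = names(x$sections[[s]]), value = unname(unlist(x$sections[[s]]))
    )
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.mwtab_document
#' @export
glance.mwtab_document <- function(x, ...) {
  tibble::tibble(
    machine_type = x$machine_type,
    n_sections = length(x$sections),
    n_samples = length(x$data$samples),
    n_rows = nrow(x$data$rows),
    study_id = x$header[["STUDY_ID"]],
    analysis_id = x$header[["ANALYSIS_ID"]]
  )
}

#' Heatmap of the deposition data matrix
#'
#' @param object An `mwtab_document`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mwtab_document <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$data$rows, -"row_name",
    names_to = "sample", values_to = "value"
  )
  df$value <- suppressWarnings(as.numeric(df$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$row_name,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = object$data$units) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
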