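#' The six-table experiment-description data model
#'
#' An `mw_dataset` holds experiment descriptions as six tables of key-based
#' records: `project`, `study`, `protocol`, `entity`, `measurement` and
#' `factor`. Each record is a flexible set of named fields following an
#' entity-attribute-value pattern: every value is text (or an ordered list of
#' text), and a field named `"X%Y"` is a descriptive attribute of field `"X"`
#' (e.g. `weight%unit` holds the units of `weight`). Cross-table references
#' use fields named `"<table>.id"`; entity lineage uses `parent_id`.
#'
#' List-valued fields are marked with [I()] so that single-element lists
#' survive the JSON round trip as arrays.
#'
#' @param tables A named list: table name -> named list of records -> named
#'   list of fields.
#' @return An object of class `mw_dataset`.
#' @export
mw_dataset <- function(tables = list()) {
  if (length(tables) == 0L) tables <- structure(list(), names = character(0))
  stopifnot(is.list(tables))
  structure(list(tables = tables), class = "mw_dataset")
}

#' Recognised table names
#' @return Character vector of the six canonical table names.
#' @export
dataset_tables <- function() {
  c("project", "study", "protocol", "entity", "measurement", "factor")
}

#' The closed set of protocol types
#'
#' A protocol plays one of five roles: `treatment` (experimental factors
#' applied to subjects), `collection` (obtaining samples from subjects),
#' `sample_prep` (operations on samples), `measurement` (assays/instruments),
#' or `storage` (where things are kept).
#'
#' @return Character vector of the five protocol types.
#' @export
protocol_types <- function() {
  c("treatment", "collection", "sample_prep", "measurement", "storage")
}

#' The two entity kinds
#' @return Character vector: subject, sample.
#' @export
entity_kinds <- function() c("subject", "sample")

#' @export
print.mw_dataset <- function(x, ...) {
  cat("<mw_dataset>\n")
  if (length(x$tables) == 0L) {
    cat("  (empty)\n")
  } else {
    for (tb in names(x$tables)) {
      cat(sprintf("  %-12s %d record(s)\n", tb, length(x$tables[[tb]])))
    }
  }
  invisible(x)
}

#' @export
length.mw_dataset <- function(x) length(x$tables)

# --- record / field accessors ------------------------------------------------

ds_table <- function(dataset, table) {
  dataset$tables[[table]] %||% structure(list(), names = character(0))
}

ds_record <- function(dataset, table, id) dataset$tables[[table]][[id]]

ds_set_field <- function(dataset, table, id, field, value) {
  if (is.null(dataset$tables[[table]])) {
    dataset$tables[[table]] <- structure(list(), names = character(0))
  }
  if (is.null(dataset$tables[[table]][[id]])) {
    dataset$tables[[table]][[id]] <- list(id = id)
  }
  dataset$tables[[table]][[id]][[field]] <- value
  dataset
}

field_values <- function(value) as.character(value)

is_list_field <- function(value) inherits(value, "AsIs") || length(value) > 1L

#' Split a field name into base and attribute
#'
#' Field names may carry one attribute marker `%`: `"weight%unit"` names the
#' attribute `unit` of the base field `weight`. At most one `%` is allowed.
#'
#' @param name A single field name.
#' @return A list with `base` and `attribute` (`NA` when the name has none).
#' @export
split_field_attribute <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(name)) {
    mwd_abort("empty field name", "mwd_field_name_error")
  }
  parts <- strsplit(name, "%", fixed = TRUE)[[1]]
  if (grepl("%", name) && (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2]))) {
    mwd_abort(
      sprintf("malformed field name '%s': expected at most one '%%'", name),
      "mwd_field_name_error"
    )
  }
  if (length(parts) == 1L) {
    list(base = parts[1], attribute = NA_character_)
  } else {
    list(base = parts[1], attribute = parts[2])
  }
}

#' Protocol types underlying an entity
#'
#' Collects the types of every protocol a given entity references through its
#' `protocol.id` field. References that do not resolve are silently excluded
#' here; [validate_references()] reports them.
#'
#' @param dataset An [mw_dataset()].
#' @param entity_id Id of an entity record.
#' @return Character vector (a set) of protocol types.
#' @export
entity_protocol_types <- function(dataset, entity_id) {
  ent <- ds_record(dataset, "entity", entity_id)
  if (is.null(ent)) {
    mwd_abort(sprintf("unknown entity '%s'", entity_id), "mwd_unknown_record_error")
  }
  refs <- ent[["protocol.id"]]
  if (is.null(refs)) return(character(0))
  types <- character(0)
  for (pid in field_values(refs)) {
    prot <- ds_record(dataset, "protocol", pid)
    if (!is.null(prot) && !is.null(prot$type)) {
      types <- c(types, field_values(prot$type)[1])
    }
  }
  sort(unique(types))
}

# --- broom-style views -------------------------------------------------------

#' Flatten a dataset to a long tibble
#'
#' One row per (table, record, field, value); list fields contribute one row
#' per element, with `position` giving the element index.
#'
#' @param x An [mw_dataset()].
#' @param ... Unused.
#' @return A tibble with columns table, record, field, position, value.
#' @export
tidy.mw_dataset <- function(x, ...) {
  rows <- list()
  for (tb in names(x$tables)) {
    for (id in names(x$tables[[tb]])) {
      rec <- x$tables[[tb]][[id]]
      for (f in names(rec)) {
        vals <- field_values(rec[[f]])
        if (length(vals) == 0L) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          table = tb, record = id, field = f,
          position = seq_along(vals), value = vals
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      table = character(), record = character(), field = character(),
      position = integer(), value = character()
    ))
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a dataset
#'
#' @param x An [mw_dataset()].
#' @param ... Unused.
#' @return A one-row tibble with per-table record counts.
#' @export
glance.mw_dataset <- function(x, ...) {
  counts <- vapply(
    dataset_tables(),
    function(tb) length(ds_table(x, tb)),
    integer(1)
  )
  out <- tibble::as_tibble(as.list(counts))
  names(out) <- paste0("n_", dataset_tables())
  out$n_tables <- length(x$tables)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
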