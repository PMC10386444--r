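# Dataset JSON I/O.
#
# The on-disk shape is object -> table name -> record id -> record object,
# with list-valued fields as JSON arrays. Values are text-only in the model;
# numbers or booleans found in input JSON are rendered to text on read
# (render_number(); booleans as "true"/"false").

coerce_field_scalar <- function(v, locus) {
  if (is.null(v)) return("")
  if (is.character(v)) return(v)
  if (is.numeric(v)) return(render_number(v))
  if (is.logical(v)) return(ifelse(v, "true", "false"))
  mwd_abort(
    sprintf("field value at %s must be text or an array of text", locus),
    "mwd_json_structure_error"
  )
}

coerce_field <- function(v, locus) {
  if (is.list(v)) {
    if (!is.null(names(v))) {
      mwd_abort(
        sprintf("nested structure at %s: field values must be text or arrays of text", locus),
        "mwd_json_structure_error"
      )
    }
    vals <- vapply(
      v,
      function(el) {
        if (is.list(el)) {
          mwd_abort(
            sprintf("nested structure at %s: list elements must be text", locus),
            "mwd_json_structure_error"
          )
        }
        coerce_field_scalar(el, locus)[1]
      },
      character(1)
    )
    return(I(vals))
  }
  coerce_field_scalar(v, locus)
}

assert_named_object <- function(x, locus) {
  if (!is.list(x)) {
    mwd_abort(sprintf("%s must be a JSON object", locus), "mwd_json_structure_error")
  }
  if (length(x) > 0L && (is.null(names(x)) || any(!nzchar(names(x))))) {
    mwd_abort(sprintf("%s must be a JSON object with named members", locus),
              "mwd_json_structure_error")
  }
  invisible(x)
}

#' Read a dataset JSON file
#'
#' Parses a six-table experiment-description JSON file (an object of objects
#' of objects). Unknown top-level table names are preserved; validation flags
#' them later.
#'
#' @param path Path to a JSON file.
#' @return An [mw_dataset()].
#' @export
read_dataset_json <- function(path) {
  if (!file.exists(path)) {
    mwd_abort(sprintf("file not found: %s", path), "mwd_io_error")
  }
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  first <- sub("^[[:space:]]*", "", txt)
  if (!startsWith(first, "{")) {
    mwd_abort(
      sprintf("%s: top level must be a JSON object of tables", path),
      "mwd_json_structure_error"
    )
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      mwd_abort(
        sprintf("malformed JSON in %s: %s", path, conditionMessage(e)),
        "mwd_json_parse_error"
      )
    }
  )
  assert_named_object(parsed, path)
  tables <- structure(list(), names = character(0))
  for (tb in names(parsed)) {
    assert_named_object(parsed[[tb]], sprintf("table '%s'", tb))
    recs <- structure(list(), names = character(0))
    for (id in names(parsed[[tb]])) {
      locus <- sprintf("%s/%s", tb, id)
      assert_named_object(parsed[[tb]][[id]], paste("record", locus))
      rec <- list()
      for (f in names(parsed[[tb]][[id]])) {
        rec[[f]] <- coerce_field(parsed[[tb]][[id]][[f]], paste0(locus, "/", f))
      }
      recs[[id]] <- rec
    }
    tables[[tb]] <- recs
  }
  mw_dataset(tables)
}

canonicalize_dataset <- function(dataset) {
  tables <- dataset$tables
  tables <- tables[order(names(tables))]
  tables <- lapply(tables, function(recs) {
    recs <- recs[order(names(recs))]
    lapply(recs, function(rec) rec[order(names(rec))])
  })
  mw_dataset(tables)
}

#' Write a dataset JSON file
#'
#' Table names, record ids and field names are written in sorted order so the
#' output is canonical; `read_dataset_json(write_dataset_json(x))` reproduces
#' `x` up to that ordering.
#'
#' @param dataset An [mw_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_json <- function(dataset, path) {
  stopifnot(inherits(dataset, "mw_dataset"))
  canon <- canonicalize_dataset(dataset)
  txt <- if (length(canon$tables) == 0L) {
    "{}"
  } else {
    as.character(jsonlite::toJSON(canon$tables, auto_unbox = TRUE, pretty = 2))
  }
  ok <- tryCatch(
    {
      writeLines(txt, path, useBytes = TRUE)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) {
    mwd_abort(sprintf("cannot write %s", path), "mwd_io_error")
  }
  invisible(path)
}
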