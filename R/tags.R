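#' The export tag grammar
#'
#' Export tags are pound-delimited column bindings placed in a `#tags` row
#' above a data table. The grammar is `[*]#<table>.<field>[=<literal>]`:
#'
#' * a leading `*` marks a list field (cell text split on `,`, whitespace
#'   stripped),
#' * `<table>` is the target table, `<field>` the target field path (the field
#'   may itself contain dots, e.g. `protocol.id`),
#' * an `=<literal>` suffix makes the tag a constant: the literal is written
#'   into every record and the column's data cells are ignored.
#'
#' @param text A single cell's text.
#' @param locus Optional description of where the cell sits (for error
#'   messages).
#' @return A list with `table`, `field`, `is_list`, `constant` (`NA` when the
#'   tag binds a column).
#' @export
parse_tag_cell <- function(text, locus = "tag cell") {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- trimws(text)
  if (!nzchar(raw)) {
    mwd_abort(sprintf("%s: empty tag", locus), "mwd_tag_syntax_error")
  }
  is_list <- startsWith(raw, "*")
  body <- if (is_list) substring(raw, 2L) else raw
  if (!startsWith(body, "#")) {
    mwd_abort(sprintf("%s: tag '%s' must start with '#'", locus, text),
              "mwd_tag_syntax_error")
  }
  body <- substring(body, 2L)
  constant <- NA_character_
  eq <- regexpr("=", body, fixed = TRUE)
  if (eq > 0L) {
    constant <- substring(body, eq + 1L)
    body <- substring(body, 1L, eq - 1L)
  }
  dot <- regexpr(".", body, fixed = TRUE)
  if (dot < 1L) {
    mwd_abort(
      sprintf("%s: tag '%s' needs '.' between table and field", locus, text),
      "mwd_tag_syntax_error"
    )
  }
  tbl <- substring(body, 1L, dot - 1L)
  fld <- substring(body, dot + 1L)
  if (!nzchar(tbl) || !nzchar(fld)) {
    mwd_abort(
      sprintf("%s: tag '%s' has an empty table or field part", locus, text),
      "mwd_tag_syntax_error"
    )
  }
  list(table = tbl, field = fld, is_list = is_list, constant = constant)
}

#' Locate tagged blocks in a grid
#'
#' A block starts at any row whose first cell is exactly `#tags`; the
#' remaining cells of that row are parsed as column tags. Data rows follow
#' until the first fully-blank row, the next `#tags` row, or a row whose
#' first cell is `#end`. Rows outside blocks are ignored. Each block must
#' contain exactly one tag whose field is `id` (the record-key column) and at
#' least one data row.
#'
#' @param grid An [mw_grid()].
#' @return A list of blocks, each a list with `tag_row`, `tags` (named by
#'   column index), `id_column`, `data_rows`.
#' @export
find_tag_blocks <- function(grid) {
  cells <- grid$cells
  n <- nrow(cells)
  blocks <- list()
  i <- 1L
  while (i <= n) {
    if (trimws(cells[i, 1L]) != "#tags") {
      i <- i + 1L
      next
    }
    tag_row <- i
    tags <- list()
    for (j in seq_len(ncol(cells))[-1L]) {
      if (nzchar(trimws(cells[tag_row, j]))) {
        tags[[as.character(j)]] <- parse_tag_cell(
          cells[tag_row, j],
          locus = grid_locus(grid, tag_row)
        )
      }
    }
    id_cols <- names(tags)[vapply(tags, function(t) t$field == "id", logical(1))]
    if (length(id_cols) != 1L) {
      mwd_abort(
        sprintf(
          "%s: block must have exactly one '.id' tag (found %d)",
          grid_locus(grid, tag_row), length(id_cols)
        ),
        "mwd_block_structure_error"
      )
    }
    j <- i + 1L
    data_rows <- integer(0)
    while (j <= n) {
      first <- trimws(cells[j, 1L])
      if (first == "#tags" || first == "#end") break
      if (all(!nzchar(trimws(cells[j, ])))) break
      data_rows <- c(data_rows, j)
      j <- j + 1L
    }
    if (length(data_rows) == 0L) {
      mwd_abort(
        sprintf("%s: tagged block has no data rows", grid_locus(grid, tag_row)),
        "mwd_empty_block_error"
      )
    }
    blocks[[length(blocks) + 1L]] <- list(
      tag_row = tag_row,
      tags = tags,
      id_column = as.integer(id_cols),
      data_rows = data_rows
    )
    i <- if (j <= n && trimws(cells[j, 1L]) == "#tags") j else j + 1L
  }
  blocks
}

split_list_cell <- function(text) {
  parts <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

#' Export one tagged block into a dataset
#'
#' Produces one record per data row, keyed by the id column's value. Each
#' tagged column writes its cell into the tag's field in the tag's table;
#' list tags split the cell on commas; constant tags write their literal into
#' every record; empty cells leave the field absent. Rows with an empty id
#' cell are skipped with a warning; a duplicate id within the block is an
#' error.
#'
#' @param block One element of [find_tag_blocks()].
#' @param grid The grid the block came from.
#' @param dataset Dataset to accumulate into (default empty).
#' @return An [mw_dataset()].
#' @export
export_block <- function(block, grid, dataset = mw_dataset()) {
  cells <- grid$cells
  id_tag <- block$tags[[as.character(block$id_column)]]
  seen <- c()
  for (row in block$data_rows) {
    id <- trimws(cells[row, block$id_column])
    if (!nzchar(id)) {
      mwd_warn(sprintf("%s: skipping row with empty id", grid_locus(grid, row)),
               "mwd_empty_id_warning")
      next
    }
    if (id %in% names(seen)) {
      mwd_abort(
        sprintf(
          "%s: duplicate id '%s' (rows %d and %d)",
          grid_locus(grid, row), id, seen[[id]], row
        ),
        "mwd_duplicate_record_error"
      )
    }
    seen[id] <- row
    touched <- character(0)
    for (jchr in names(block$tags)) {
      tag <- block$tags[[jchr]]
      j <- as.integer(jchr)
      raw <- if (!is.na(tag$constant)) tag$constant else trimws(cells[row, j])
      if (!nzchar(raw)) next
      value <- if (tag$is_list) I(split_list_cell(raw)) else raw
      if (tag$field == "id") value <- id
      dataset <- ds_set_field(dataset, tag$table, id, tag$field, value)
      touched <- unique(c(touched, tag$table))
    }
    for (tb in touched) {
      dataset$tables[[tb]][[id]][["id"]] <- id
    }
  }
  dataset
}
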