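#' Grids: rectangular text snapshots of one sheet
#'
#' A grid is the raw substrate the tagging system works on: every cell of one
#' sheet of a tabular file, as text (blank cells are the empty string). Grids
#' are rectangular by construction and trailing fully-blank rows and columns
#' are trimmed on read.
#'
#' @param cells A character matrix.
#' @param source Path of the file the grid came from (or `NA`).
#' @param sheet Sheet name for workbook sources (or `NA` for CSV).
#' @return An object of class `mw_grid`.
#' @export
mw_grid <- function(cells, source = NA_character_, sheet = NA_character_) {
  stopifnot(is.matrix(cells))
  storage.mode(cells) <- "character"
  cells[is.na(cells)] <- ""
  structure(
    list(cells = cells, source = source, sheet = sheet),
    class = "mw_grid"
  )
}

#' @export
dim.mw_grid <- function(x) dim(x$cells)

#' @export
print.mw_grid <- function(x, ...) {
  cat(sprintf(
    "<mw_grid> %d x %d cells from %s%s\n",
    nrow(x$cells), ncol(x$cells),
    if (is.na(x$source)) "<memory>" else x$source,
    if (is.na(x$sheet)) "" else paste0(" [", x$sheet, "]")
  ))
  invisible(x)
}

# Locus string used in error messages: "file [sheet] row N".
grid_locus <- function(grid, row = NULL) {
  src <- if (is.na(grid$source)) "<memory>" else grid$source
  sh <- if (is.na(grid$sheet)) "" else paste0(" [", grid$sheet, "]")
  rw <- if (is.null(row)) "" else paste0(" row ", row)
  paste0(src, sh, rw)
}

#' Parse a source specification
#'
#' Sources are given as `"path"` or `"path:sheetname"`. The sheet suffix is
#' only split off when the bare path does not itself name an existing file,
#' so paths containing colons still resolve.
#'
#' @param spec A single string.
#' @return A list with elements `path` and `sheet` (`NA` when absent).
#' @export
parse_source_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  if (file.exists(spec) || !grepl(":", spec)) {
    return(list(path = spec, sheet = NA_character_))
  }
  pos <- regexpr(":[^:]*$", spec)
  list(
    path = substr(spec, 1L, pos - 1L),
    sheet = substr(spec, pos + 1L, nchar(spec))
  )
}

is_xlsx <- function(path) grepl("\\.xlsx$", path, ignore.case = TRUE)

trim_grid <- function(cells) {
  if (length(cells) == 0L) return(matrix(character(0), 0L, 0L))
  filled_row <- apply(cells, 1L, function(r) any(nzchar(r)))
  filled_col <- apply(cells, 2L, function(c) any(nzchar(c)))
  last_row <- if (any(filled_row)) max(which(filled_row)) else 0L
  last_col <- if (any(filled_col)) max(which(filled_col)) else 0L
  cells[seq_len(last_row), seq_len(last_col), drop = FALSE]
}

#' Read one sheet of a tabular file as a grid
#'
#' CSV files (RFC 4180, comma delimiter, UTF-8) are read whole; XLSX workbooks
#' need a sheet, defaulting to `"#export"` when none is given. All cells come
#' back as text; blanks are `""`; trailing fully-blank rows/columns are
#' trimmed.
#'
#' @param spec A path, `"path:sheet"` string, or the list from
#'   [parse_source_spec()].
#' @param sheet Optional sheet name overriding the one in `spec`.
#' @return An [mw_grid()].
#' @export
read_grid <- function(spec, sheet = NULL) {
  if (is.character(spec)) spec <- parse_source_spec(spec)
  path <- spec$path
  if (!is.null(sheet)) spec$sheet <- sheet
  if (!file.exists(path)) {
    mwd_abort(sprintf("file not found: %s", path), "mwd_io_error")
  }
  if (is_xlsx(path)) {
    sheets <- readxl::excel_sheets(path)
    want <- if (is.na(spec$sheet)) "#export" else spec$sheet
    if (!want %in% sheets) {
      mwd_abort(
        sprintf(
          "no sheet named '%s' in %s (available: %s)",
          want, path, paste(sheets, collapse = ", ")
        ),
        "mwd_sheet_error"
      )
    }
    df <- suppressMessages(readxl::read_excel(
      path, sheet = want, col_names = FALSE, col_types = "text",
      .name_repair = "minimal"
    ))
    cells <- matrix(
      cell_text(unlist(df, use.names = FALSE)),
      nrow = nrow(df), ncol = ncol(df)
    )
    return(mw_grid(trim_grid(cells), source = path, sheet = want))
  }
  if (!is.na(spec$sheet)) {
    mwd_abort(
      sprintf("sheet '%s' given for CSV source %s", spec$sheet, path),
      "mwd_source_spec_error"
    )
  }
  df <- suppressWarnings(readr::read_csv(
    path, col_names = FALSE, col_types = readr::cols(.default = "c"),
    na = character(), progress = FALSE, show_col_types = FALSE,
    name_repair = "minimal"
  ))
  cells <- if (nrow(df) == 0L) {
    matrix(character(0), 0L, 0L)
  } else {
    matrix(cell_text(unlist(df, use.names = FALSE)), nrow = nrow(df), ncol = ncol(df))
  }
  mw_grid(trim_grid(cells), source = path, sheet = NA_character_)
}

#' Write a grid as CSV
#'
#' Cells are written verbatim (RFC 4180 quoting, no header row).
#'
#' @param grid An [mw_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  df <- as.data.frame(grid$cells, stringsAsFactors = FALSE)
  utils::write.table(
    df, path, sep = ",", row.names = FALSE, col.names = FALSE,
    qmethod = "double", fileEncoding = "UTF-8"
  )
  invisible(path)
}
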