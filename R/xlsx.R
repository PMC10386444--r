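# Minimal ECMA-376 workbook writer.
#
# Writes multi-sheet .xlsx files whose cells are all inline strings, which is
# exactly what the text-only tagging substrate needs: what is written is what
# read_grid() reads back, with no number-format round-trip involved. Archive
# member timestamps are pinned so the same content always produces the same
# bytes.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

col_letter <- function(j) {
  out <- ""
  while (j > 0L) {
    r <- (j - 1L) %% 26L
    out <- paste0(LETTERS[r + 1L], out)
    j <- (j - 1L) %/% 26L
  }
  out
}

sheet_xml <- function(cells) {
  rows <- character(0)
  if (nrow(cells) > 0L) {
    rows <- vapply(seq_len(nrow(cells)), function(i) {
      cs <- character(0)
      for (j in seq_len(ncol(cells))) {
        v <- cells[i, j]
        if (!nzchar(v)) next
        cs <- c(cs, sprintf(
          '<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
          col_letter(j), i, xml_escape(v)
        ))
      }
      sprintf('<row r="%d">%s</row>', i, paste(cs, collapse = ""))
    }, character(1))
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>"
  )
}

#' Write a multi-sheet XLSX workbook of text cells
#'
#' Every cell is stored as an inline string, so the workbook round-trips
#' byte-for-byte through [read_grid()]. Output is deterministic: identical
#' input yields identical file bytes.
#'
#' @param sheets Named list; each element a character matrix (or [mw_grid()])
#'   of cell text. Names become sheet names.
#' @param path Output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
write_xlsx_grids <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) > 0L, !is.null(names(sheets)))
  sheets <- lapply(sheets, function(s) if (inherits(s, "mw_grid")) s$cells else s)
  stage <- tempfile("xlsx_stage")
  dir.create(file.path(stage, "xl", "worksheets"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "_rels"), recursive = TRUE)

  n <- length(sheets)
  overrides <- vapply(seq_len(n), function(i) sprintf(
    '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    i
  ), character(1))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(overrides, collapse = ""), "</Types>"
  ), file.path(stage, "[Content_Types].xml"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"
  ), file.path(stage, "_rels", ".rels"))

  sheet_entries <- vapply(seq_len(n), function(i) sprintf(
    '<sheet name="%s" sheetId="%d" r:id="rId%d"/>', xml_escape(names(sheets)[i]), i, i
  ), character(1))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<sheets>", paste(sheet_entries, collapse = ""), "</sheets></workbook>"
  ), file.path(stage, "xl", "workbook.xml"))

  rels <- vapply(seq_len(n), function(i) sprintf(
    '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
    i, i
  ), character(1))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(rels, collapse = ""), "</Relationships>"
  ), file.path(stage, "xl", "_rels", "workbook.xml.rels"))

  for (i in seq_len(n)) {
    writeLines(sheet_xml(sheets[[i]]), file.path(stage, "xl", "worksheets", sprintf("sheet%d.xml", i)))
  }

  members <- c(
    "[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
    "xl/_rels/workbook.xml.rels",
    sprintf("xl/worksheets/sheet%d.xml", seq_len(n))
  )
  # pin mtimes so the archive is byte-identical across runs
  for (m in members) {
    Sys.setFileTime(file.path(stage, m), as.POSIXct("2020-01-01 00:00:00", tz = "UTC"))
  }
  if (file.exists(path)) unlink(path)
  zip::zip(normalizePath(path, mustWork = FALSE), files = members, root = stage,
           mode = "mirror", include_directories = FALSE)
  unlink(stage, recursive = TRUE)
  invisible(path)
}
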