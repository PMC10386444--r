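# mwTab serialization.
#
# Tab-delimited dialect (normative for this implementation):
#   line 1   : "#METABOLOMICS WORKBENCH" + tab-separated KEY:VALUE tokens
#              (STUDY_ID, ANALYSIS_ID, VERSION, CREATED_ON)
#   sections : "#SECTION" banner, then one "<PFX>:<KEY>\t<value>" line per key
#              (PR, ST, SU, CO, TR, SP, AN, MS, NM prefixes)
#   data     : "#<BLOCK>" banner, "<BLOCK>:UNITS\t<units>", "<BLOCK>_START",
#              "Samples\t..." and "Factors\t..." rows, one row per collate
#              value, "<BLOCK>_END"
#   features : "#METABOLITES" banner with METABOLITES_START/_END and a
#              "metabolite_name" header row (ms/nmr only)
#   trailer  : "#END"

row_label_key <- function(machine_type) {
  if (machine_type == "nmr_binned") "Bin" else "Metabolite"
}

#' Write an mwTab document as JSON
#'
#' @param doc An `mwtab_document`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mwtab_json <- function(doc, path) {
  out <- list()
  out[[MWTAB_HEADER_SECTION]] <- as.list(doc$header)
  for (s in names(doc$sections)) out[[s]] <- as.list(doc$sections[[s]])
  label <- row_label_key(doc$machine_type)
  rows <- doc$data$rows
  data_rows <- lapply(seq_len(nrow(rows)), function(i) {
    r <- as.list(rows[i, ])
    names(r)[1] <- label
    r
  })
  out[[doc$data$name]] <- list(
    Units = doc$data$units,
    Samples = I(doc$data$samples),
    Factors = I(doc$data$factors),
    Data = data_rows
  )
  if (!is.null(doc$metabolites)) {
    met_rows <- lapply(seq_len(nrow(doc$metabolites)), function(i) {
      r <- as.list(doc$metabolites[i, ])
      names(r)[1] <- "metabolite_name"
      r
    })
    out[["METABOLITES"]] <- list(Data = met_rows)
  }
  writeLines(
    as.character(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = 2)),
    path, useBytes = TRUE
  )
  invisible(path)
}

#' Render an mwTab document in the tab-delimited dialect
#'
#' @param doc An `mwtab_document`.
#' @return A single string (lines joined with `\n`).
#' @export
write_mwtab_txt <- function(doc) {
  lines <- character(0)
  lines <- c(lines, paste(
    c("#METABOLOMICS WORKBENCH",
      paste0(names(doc$header), ":", unname(doc$header))),
    collapse = "\t"
  ))
  for (s in names(doc$sections)) {
    pfx <- SECTION_PREFIXES[[s]]
    if (is.null(pfx)) pfx <- substr(gsub("[^A-Z]", "", s), 1, 2)
    lines <- c(lines, paste0("#", s))
    sec <- doc$sections[[s]]
    for (k in names(sec)) {
      lines <- c(lines, paste0(pfx, ":", k, "\t", sec[[k]]))
    }
  }
  blk <- doc$data$name
  lines <- c(lines, paste0("#", blk))
  lines <- c(lines, paste0(blk, ":UNITS\t", doc$data$units))
  lines <- c(lines, paste0(blk, "_START"))
  lines <- c(lines, paste(c("Samples", doc$data$samples), collapse = "\t"))
  lines <- c(lines, paste(c("Factors", doc$data$factors), collapse = "\t"))
  rows <- doc$data$rows
  for (i in seq_len(nrow(rows))) {
    lines <- c(lines, paste(unlist(rows[i, ]), collapse = "\t"))
  }
  lines <- c(lines, paste0(blk, "_END"))
  if (!is.null(doc$metabolites)) {
    lines <- c(lines, "#METABOLITES", "METABOLITES_START")
    lines <- c(lines, paste(c("metabolite_name", names(doc$metabolites)[-1]),
                            collapse = "\t"))
    for (i in seq_len(nrow(doc$metabolites))) {
      lines <- c(lines, paste(unlist(doc$metabolites[i, ]), collapse = "\t"))
    }
    lines <- c(lines, "METABOLITES_END")
  }
  lines <- c(lines, "#END")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write both mwTab output files
#'
#' Given an output stem `"output"`, writes `output.json` and `output.txt`.
#'
#' @param doc An `mwtab_document`.
#' @param stem Output path stem (no extension).
#' @return Character vector of the two paths, invisibly.
#' @export
write_mwtab_files <- function(doc, stem) {
  json_path <- paste0(stem, ".json")
  txt_path <- paste0(stem, ".txt")
  write_mwtab_json(doc, json_path)
  writeLines(sub("\n$", "", write_mwtab_txt(doc)), txt_path, useBytes = TRUE)
  invisible(c(json = json_path, txt = txt_path))
}

mwtab_dialect_error <- function(lineno, why) {
  mwd_abort(sprintf("mwTab text line %d: %s", lineno, why), "mwd_mwtab_dialect_error")
}

split_pad <- function(line, n) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < n) parts <- c(parts, rep("", n - length(parts)))
  parts
}

#' Parse mwTab tab-delimited text
#'
#' Inverse of [write_mwtab_txt()] on its own output.
#'
#' @param text A single string or a character vector of lines.
#' @return An `mwtab_document`.
#' @export
parse_mwtab_txt <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  lines <- lines[nzchar(lines) | seq_along(lines) < length(lines)]
  if (length(lines) == 0L || !startsWith(lines[1], "#METABOLOMICS WORKBENCH")) {
    mwtab_dialect_error(1L, "expected '#METABOLOMICS WORKBENCH' header line")
  }
  toks <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  header <- character(0)
  for (t in toks) {
    p <- regexpr(":", t, fixed = TRUE)
    if (p < 1L) mwtab_dialect_error(1L, sprintf("malformed header token '%s'", t))
    header[[substr(t, 1, p - 1)]] <- substring(t, p + 1)
  }
  sections <- list()
  data <- NULL
  metabolites <- NULL
  machine_type <- NA_character_
  i <- 2L
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    if (!nzchar(line)) { i <- i + 1L; next }
    if (!startsWith(line, "#")) {
      mwtab_dialect_error(i, sprintf("expected a section banner, got '%s'", line))
    }
    banner <- substring(line, 2L)
    if (banner == "END") break
    if (grepl("_DATA$", banner)) {
      machine_type <- switch(banner,
        MS_METABOLITE_DATA = "ms", NMR_METABOLITE_DATA = "nmr",
        NMR_BINNED_DATA = "nmr_binned",
        mwtab_dialect_error(i, sprintf("unknown data block '%s'", banner))
      )
      i <- i + 1L
      units <- ""
      if (i <= n && startsWith(lines[i], paste0(banner, ":UNITS"))) {
        units <- split_pad(lines[i], 2L)[2]
        i <- i + 1L
      }
      if (i > n || lines[i] != paste0(banner, "_START")) {
        mwtab_dialect_error(i, sprintf("expected %s_START", banner))
      }
      i <- i + 1L
      if (i > n || !startsWith(lines[i], "Samples")) {
        mwtab_dialect_error(i, "expected Samples row")
      }
      samples <- strsplit(lines[i], "\t", fixed = TRUE)[[1]][-1]
      i <- i + 1L
      if (i > n || !startsWith(lines[i], "Factors")) {
        mwtab_dialect_error(i, "expected Factors row")
      }
      factors <- split_pad(lines[i], length(samples) + 1L)[-1]
      i <- i + 1L
      row_list <- list()
      repeat {
        if (i > n) mwtab_dialect_error(i, sprintf("missing %s_END", banner))
        if (lines[i] == paste0(banner, "_END")) break
        parts <- split_pad(lines[i], length(samples) + 1L)
        row_list[[length(row_list) + 1L]] <- parts
        i <- i + 1L
      }
      rows <- tibble::tibble(row_name = vapply(row_list, `[`, character(1), 1L))
      for (j in seq_along(samples)) {
        rows[[samples[j]]] <- vapply(row_list, `[`, character(1), j + 1L)
      }
      data <- list(name = banner, units = units, samples = samples,
                   factors = factors, rows = rows)
      i <- i + 1L
      next
    }
    if (banner == "METABOLITES") {
      i <- i + 1L
      if (i > n || lines[i] != "METABOLITES_START") {
        mwtab_dialect_error(i, "expected METABOLITES_START")
      }
      i <- i + 1L
      hdr <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      i <- i + 1L
      row_list <- list()
      repeat {
        if (i > n) mwtab_dialect_error(i, "missing METABOLITES_END")
        if (lines[i] == "METABOLITES_END") break
        row_list[[length(row_list) + 1L]] <- split_pad(lines[i], length(hdr))
        i <- i + 1L
      }
      metabolites <- tibble::tibble(
        row_name = vapply(row_list, `[`, character(1), 1L)
      )
      for (j in seq_along(hdr)[-1L]) {
        metabolites[[hdr[j]]] <- vapply(row_list, `[`, character(1), j)
      }
      i <- i + 1L
      next
    }
    # descriptive section
    sec <- character(0)
    i <- i + 1L
    while (i <= n && !startsWith(lines[i], "#")) {
      parts <- split_pad(lines[i], 2L)
      p <- regexpr(":", parts[1], fixed = TRUE)
      if (p < 1L) mwtab_dialect_error(i, sprintf("malformed prefixed line '%s'", parts[1]))
      sec[[substring(parts[1], p + 1L)]] <- parts[2]
      i <- i + 1L
    }
    sections[[banner]] <- sec
  }
  if (is.null(data)) {
    mwtab_dialect_error(n, "no data block found")
  }
  structure(
    list(machine_type = machine_type, header = header, sections = sections,
         data = data, metabolites = metabolites),
    class = "mwtab_document"
  )
}

#' Convert a dataset to mwTab files
#'
#' The one-call conversion pipeline: load directives (with optional update/
#' override files), build the document, and write `<stem>.json` and
#' `<stem>.txt`.
#'
#' @param dataset An [mw_dataset()] or a path to a dataset JSON file.
#' @param machine_type One of `ms`, `nmr`, `nmr_binned`.
#' @param stem Output path stem.
#' @param update,override Optional directive JSON files.
#' @param created_on Optional fixed `CREATED_ON` date.
#' @param force Skip the mwTab readiness gate.
#' @return The `mwtab_document`, invisibly.
#' @export
convert_mwtab <- function(dataset, machine_type, stem, update = NULL,
                          override = NULL, created_on = NULL, force = FALSE) {
  if (is.character(dataset)) dataset <- read_dataset_json(dataset)
  directives <- load_directives(machine_type, update = update, override = override)
  doc <- build_mwtab(dataset, machine_type, directives = directives,
                     created_on = created_on, force = force)
  write_mwtab_files(doc, stem)
  invisible(doc)
}
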