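# Automation: turn an untagged data table into a tagged grid by matching its
# header row against a set of directives.

#' Build an automation directive
#'
#' @param header Header text the directive matches (fuzzily, see
#'   [match_header()]).
#' @param tag Export tag text to place on the matched column; must parse under
#'   the tag grammar.
#' @param required If `TRUE`, a missing header is an error instead of a
#'   warning.
#' @return A list of class `mw_automation_directive`.
#' @export
automation_directive <- function(header, tag, required = FALSE) {
  parse_tag_cell(tag, locus = sprintf("automation tag for '%s'", header))
  structure(
    list(header = header, tag = tag, required = isTRUE(required)),
    class = "mw_automation_directive"
  )
}

truthy <- function(x) tolower(trimws(x)) %in% c("true", "t", "yes", "1")

# Directive tables are plain header tables: a header row containing at least
# "header" and "tag" (optional "required"), then one directive per row.
parse_automation_grid <- function(grid) {
  cells <- grid$cells
  hdr_row <- which(apply(cells, 1L, function(r) any(nzchar(trimws(r)))))[1]
  if (is.na(hdr_row)) return(list())
  headers <- tolower(trimws(cells[hdr_row, ]))
  hcol <- match("header", headers)
  tcol <- match("tag", headers)
  rcol <- match("required", headers)
  if (is.na(hcol) || is.na(tcol)) {
    mwd_abort(
      sprintf("%s: automation table needs 'header' and 'tag' columns",
              grid_locus(grid, hdr_row)),
      "mwd_directive_error"
    )
  }
  out <- list()
  for (i in seq_len(nrow(cells))) {
    if (i <= hdr_row) next
    h <- trimws(cells[i, hcol])
    t <- trimws(cells[i, tcol])
    if (!nzchar(h) && !nzchar(t)) next
    out[[length(out) + 1L]] <- automation_directive(
      h, t,
      required = !is.na(rcol) && truthy(cells[i, rcol])
    )
  }
  out
}

parse_automation_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(d) {
    automation_directive(
      d$header %||% mwd_abort("automation directive without 'header'", "mwd_directive_error"),
      d$tag %||% mwd_abort("automation directive without 'tag'", "mwd_directive_error"),
      required = isTRUE(d$required)
    )
  })
}

#' Read automation directives from a file
#'
#' Accepts a JSON array of `{header, tag, required}` objects, or a tabular
#' source (CSV, or XLSX sheet, default sheet `#automate`) holding a
#' header/tag/required table.
#'
#' @param spec A path, `"path:sheet"` string, or parsed source spec.
#' @return List of [automation_directive()]s.
#' @export
read_automation_directives <- function(spec) {
  if (is.character(spec)) spec <- parse_source_spec(spec)
  if (grepl("\\.json$", spec$path, ignore.case = TRUE)) {
    return(parse_automation_json(spec$path))
  }
  sheet <- if (is_xlsx(spec$path) && is.na(spec$sheet)) "#automate" else spec$sheet
  parse_automation_grid(read_grid(list(path = spec$path, sheet = sheet)))
}

#' Insert export tags into an untagged grid
#'
#' The first non-blank row of `grid` is taken as the header row of a single
#' data table. Each directive is matched against the headers with
#' [match_header()]; matched columns receive the directive's tag. The result
#' is a tagged grid ready for [find_tag_blocks()]: a marker column is
#' prepended, a `#tags` row replaces the header row, and the data rows
#' follow. Unmatched non-required directives are skipped with a warning;
#' unmatched required directives are an error.
#'
#' @param grid An untagged [mw_grid()].
#' @param directives List of [automation_directive()]s.
#' @return A tagged [mw_grid()].
#' @export
apply_automation <- function(grid, directives) {
  cells <- grid$cells
  nonblank <- which(apply(cells, 1L, function(r) any(nzchar(trimws(r)))))
  if (length(nonblank) == 0L) {
    mwd_abort(sprintf("%s: nothing to tag in an empty grid", grid_locus(grid)),
              "mwd_directive_error")
  }
  hdr_row <- nonblank[1]
  headers <- trimws(cells[hdr_row, ])
  tag_cells <- rep("", ncol(cells))
  for (d in directives) {
    m <- match_header(d$header, headers)
    if (is.null(m) || !nzchar(m$candidate)) {
      if (d$required) {
        mwd_abort(
          sprintf("%s: required header '%s' not found", grid_locus(grid, hdr_row), d$header),
          "mwd_missing_header_error"
        )
      }
      mwd_warn(
        sprintf("%s: automation header '%s' matched nothing; skipped",
                grid_locus(grid, hdr_row), d$header),
        "mwd_unmatched_header_warning"
      )
      next
    }
    tag_cells[m$index] <- d$tag
  }
  data_rows <- cells[setdiff(seq_len(nrow(cells)), seq_len(hdr_row)), , drop = FALSE]
  out <- rbind(
    c("#tags", tag_cells),
    cbind(rep("", nrow(data_rows)), data_rows)
  )
  mw_grid(out, source = grid$source, sheet = grid$sheet)
}
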