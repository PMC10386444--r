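#' Merge two datasets
#'
#' Table-wise, record-wise union. Records sharing an id merge field-wise; when
#' the same field holds different values the later source (`b`) wins and a
#' conflict warning is emitted.
#'
#' @param a,b [mw_dataset()]s; `b` is the later source.
#' @return The merged [mw_dataset()].
#' @export
merge_datasets <- function(a, b) {
  out <- a
  for (tb in names(b$tables)) {
    if (is.null(out$tables[[tb]])) {
      out$tables[[tb]] <- b$tables[[tb]]
      next
    }
    for (id in names(b$tables[[tb]])) {
      new <- b$tables[[tb]][[id]]
      old <- out$tables[[tb]][[id]]
      if (is.null(old)) {
        out$tables[[tb]][[id]] <- new
        next
      }
      for (f in names(new)) {
        if (f %in% names(old) && !identical(field_values(old[[f]]), field_values(new[[f]]))) {
          mwd_warn(
            sprintf("merge conflict at %s/%s/%s: keeping later value", tb, id, f),
            "mwd_merge_conflict_warning"
          )
        }
        old[[f]] <- new[[f]]
      }
      out$tables[[tb]][[id]] <- old
    }
  }
  out
}

# Export every tagged block of a grid into one dataset.
export_grid <- function(grid) {
  blocks <- find_tag_blocks(grid)
  dataset <- mw_dataset()
  for (b in blocks) {
    dataset <- merge_datasets(dataset, export_block(b, grid))
  }
  dataset
}

grid_has_tags <- function(grid) {
  nrow(grid$cells) > 0L && any(trimws(grid$cells[, 1L]) == "#tags")
}

# Resolve the grid to export from one source, applying automation when the
# source is untagged and automation directives are available. Returns
# list(grid, parts, automated_grid or NULL).
resolve_source_grid <- function(spec, automate_spec = NULL) {
  parts <- character(0)
  directives <- NULL
  if (!is.null(automate_spec)) {
    directives <- read_automation_directives(automate_spec)
  }
  if (is_xlsx(spec$path)) {
    sheets <- readxl::excel_sheets(spec$path)
    if (is.null(directives) && "#automate" %in% sheets) {
      directives <- parse_automation_grid(
        read_grid(list(path = spec$path, sheet = "#automate"))
      )
    }
    if (is.na(spec$sheet)) {
      if ("#export" %in% sheets) {
        spec$sheet <- "#export"
      } else if (!is.null(directives)) {
        plain <- sheets[!startsWith(sheets, "#")]
        if (length(plain) == 0L) {
          mwd_abort(
            sprintf("%s: no '#export' sheet and no untagged data sheet", spec$path),
            "mwd_sheet_error"
          )
        }
        spec$sheet <- plain[1]
      }
    }
  }
  grid <- read_grid(spec)
  automated <- NULL
  if (!grid_has_tags(grid)) {
    if (is.null(directives)) {
      mwd_abort(
        sprintf("%s: no '#tags' rows and no automation directives", grid_locus(grid)),
        "mwd_block_structure_error"
      )
    }
    grid <- apply_automation(grid, directives)
    automated <- grid
    parts <- c(parts, "automation")
  }
  parts <- c("export", parts)
  list(grid = grid, parts = parts, automated = automated)
}

# Modification directives attached to a source workbook ('#modify' sheet).
source_modifications <- function(spec) {
  if (!is_xlsx(spec$path)) return(list())
  if (!"#modify" %in% readxl::excel_sheets(spec$path)) return(list())
  parse_modification_grid(read_grid(list(path = spec$path, sheet = "#modify")))
}

#' Extract a dataset from tagged tabular sources
#'
#' For each source: load its grid (XLSX defaults to the `#export` sheet;
#' untagged grids are tagged via automation directives, taken from
#' `automate` or the source's own `#automate` sheet), find the tagged blocks
#' and export them. Sources are merged in order; modification directives
#' (from `modify` or each source's `#modify` sheet) are applied next, then
#' deletes. The returned dataset carries a `tagging_parts` attribute naming
#' which of the three tagging-system parts (export, automation, modification)
#' were exercised.
#'
#' @param sources Character vector of source specs (`"path"` or
#'   `"path:sheet"`), or a list of parsed specs.
#' @param automate Optional automation directive source.
#' @param modify Optional modification directive source.
#' @param deletes List of [delete_selector()]s.
#' @param save_export Optional path: the automation-tagged grid is saved there
#'   (CSV, or XLSX if the path ends in `.xlsx`).
#' @param output Optional path: the dataset is also written as JSON.
#' @return An [mw_dataset()].
#' @export
extract_dataset <- function(sources, automate = NULL, modify = NULL,
                            deletes = list(), save_export = NULL, output = NULL) {
  stopifnot(length(sources) >= 1L)
  if (is.character(sources)) sources <- lapply(sources, parse_source_spec)
  dataset <- mw_dataset()
  parts <- character(0)
  mods <- list()
  n_saved <- 0L
  for (spec in sources) {
    res <- resolve_source_grid(spec, automate_spec = automate)
    parts <- unique(c(parts, res$parts))
    dataset <- merge_datasets(dataset, export_grid(res$grid))
    mods <- c(mods, source_modifications(spec))
    if (!is.null(save_export) && !is.null(res$automated)) {
      n_saved <- n_saved + 1L
      path <- if (n_saved == 1L) {
        save_export
      } else {
        sub("(\\.[^.]+)?$", sprintf("_%d\\1", n_saved), save_export)
      }
      if (is_xlsx(path)) {
        write_xlsx_grids(stats::setNames(list(res$automated$cells), "#export"), path)
      } else {
        write_grid_csv(res$automated, path)
      }
    }
  }
  if (!is.null(modify)) {
    mods <- c(mods, read_modification_directives(modify))
  }
  if (length(mods) > 0L) {
    dataset <- apply_modifications(dataset, mods)
    parts <- c(parts, "modification")
  }
  if (length(deletes) > 0L) {
    dataset <- delete_entries(dataset, deletes)
  }
  attr(dataset, "tagging_parts") <- parts
  if (!is.null(output)) write_dataset_json(dataset, output)
  dataset
}
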