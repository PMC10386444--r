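# Protocol-dependent schemas (PD schemas).
#
# A PD schema declares per-protocol field requirements organized in a
# parent_protocol inheritance table: each protocol may name a parent, and a
# child inherits its parent's effective requirements. Compilation walks the
# ancestry: type resolves to the protocol's own type or the nearest
# ancestor's; required_fields is the union along the chain (ancestor-first,
# then alphabetical within each level); allowed_values are per-field, child
# overriding parent.

new_pds_entry <- function(parent = NA_character_, type = NA_character_,
                          required_fields = character(0),
                          optional_fields = character(0),
                          allowed_values = list()) {
  list(
    parent = parent, type = type,
    required_fields = required_fields, optional_fields = optional_fields,
    allowed_values = allowed_values
  )
}

pds_entry_from_record <- function(rec) {
  allowed <- list()
  for (f in names(rec)) {
    sp <- split_field_attribute(f)
    if (!is.na(sp$attribute) && sp$base == "allowed_values") {
      allowed[[sp$attribute]] <- field_values(rec[[f]])
    }
  }
  new_pds_entry(
    parent = if (!is.null(rec$parent_id) && nzchar(rec$parent_id)) rec$parent_id else NA_character_,
    type = if (!is.null(rec$type) && nzchar(rec$type)) rec$type else NA_character_,
    required_fields = if (is.null(rec$required_fields)) character(0) else field_values(rec$required_fields),
    optional_fields = if (is.null(rec$optional_fields)) character(0) else field_values(rec$optional_fields),
    allowed_values = allowed
  )
}

#' Read a PD schema
#'
#' Accepts either a JSON file (a map protocol name -> entry with optional
#' `parent_id`, `type`, `required_fields`, `optional_fields`,
#' `allowed_values`; a dataset-shaped file with a `parent_protocol` table is
#' also accepted) or a tagged tabular file whose blocks target a
#' `parent_protocol` table. In tabular form, allowed values are expressed via
#' the attribute-field convention: a list column tagged
#' `*#parent_protocol.allowed_values%<field>`.
#'
#' @param spec Path or `"path:sheet"` source spec.
#' @return A named list of raw PD-schema entries (class `mw_pds`).
#' @export
read_pd_schema <- function(spec) {
  if (is.character(spec)) spec <- parse_source_spec(spec)
  if (grepl("\\.json$", spec$path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(spec$path, simplifyVector = FALSE)
    assert_named_object(raw, spec$path)
    if ("parent_protocol" %in% names(raw)) raw <- raw[["parent_protocol"]]
    entries <- lapply(raw, function(e) {
      rec <- lapply(e, function(v) if (is.list(v) && is.null(names(v))) I(unlist(v)) else v)
      if (!is.null(e$allowed_values)) {
        ent <- pds_entry_from_record(rec[setdiff(names(rec), "allowed_values")])
        ent$allowed_values <- lapply(e$allowed_values, function(v) unlist(v))
        ent
      } else {
        pds_entry_from_record(rec)
      }
    })
    return(structure(entries, class = "mw_pds"))
  }
  grid <- read_grid(spec)
  dataset <- export_grid(grid)
  tab <- ds_table(dataset, "parent_protocol")
  if (length(tab) == 0L) {
    mwd_abort(
      sprintf("%s: no 'parent_protocol' records found", spec$path),
      "mwd_pds_error"
    )
  }
  structure(lapply(tab, pds_entry_from_record), class = "mw_pds")
}

#' Compile a PD schema
#'
#' Resolves each protocol's effective requirements by walking its ancestry.
#' Parent links must form a forest; every protocol must resolve a type
#' somewhere along its chain.
#'
#' @param raw A raw PD schema ([read_pd_schema()] output or an equivalently
#'   shaped named list).
#' @return A named list of effective entries (class `mw_compiled_pds`), each
#'   with `type`, `required_fields`, `optional_fields`, `allowed_values`.
#' @export
compile_pd_schema <- function(raw) {
  names_all <- names(raw)
  chain_of <- function(name) {
    chain <- character(0)
    cur <- name
    while (!is.na(cur)) {
      if (cur %in% chain) {
        loop <- c(chain[which(chain == cur):length(chain)], cur)
        mwd_abort(
          sprintf("parent_protocol cycle: %s", paste(loop, collapse = " -> ")),
          "mwd_pds_cycle_error"
        )
      }
      chain <- c(chain, cur)
      if (!cur %in% names_all) break  # dangling parent: chain just ends
      cur <- raw[[cur]]$parent %||% NA_character_
      if (!is.na(cur) && !nzchar(cur)) cur <- NA_character_
    }
    chain
  }
  effective <- list()
  for (name in names_all) {
    chain <- chain_of(name)           # self first, root last
    known <- chain[chain %in% names_all]
    types <- vapply(known, function(p) raw[[p]]$type %||% NA_character_, character(1))
    type <- types[!is.na(types)][1]
    if (is.na(type) || is.null(type)) {
      mwd_abort(
        sprintf("protocol '%s' resolves no type along its ancestry", name),
        "mwd_pds_untyped_error"
      )
    }
    required <- character(0)
    optional <- character(0)
    allowed <- list()
    for (p in rev(known)) {           # ancestor-first
      required <- c(required, sort(setdiff(raw[[p]]$required_fields, required)))
      optional <- c(optional, sort(setdiff(raw[[p]]$optional_fields, optional)))
      for (f in names(raw[[p]]$allowed_values)) {
        allowed[[f]] <- raw[[p]]$allowed_values[[f]]  # child overrides parent
      }
    }
    effective[[name]] <- list(
      type = unname(type), required_fields = required,
      optional_fields = optional, allowed_values = allowed
    )
  }
  structure(effective, class = "mw_compiled_pds")
}

#' Write a PD schema as JSON
#'
#' Convenience converter from the tabular parent_protocol form to the JSON
#' form (the `validate pds-to-json` subcommand).
#'
#' @param pds A raw PD schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pd_schema_json <- function(pds, path) {
  out <- lapply(pds, function(e) {
    x <- list()
    if (!is.na(e$parent)) x$parent_id <- e$parent
    if (!is.na(e$type)) x$type <- e$type
    if (length(e$required_fields)) x$required_fields <- I(e$required_fields)
    if (length(e$optional_fields)) x$optional_fields <- I(e$optional_fields)
    if (length(e$allowed_values)) x$allowed_values <- lapply(e$allowed_values, I)
    x
  })
  writeLines(
    as.character(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = 2)),
    path, useBytes = TRUE
  )
  invisible(path)
}
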