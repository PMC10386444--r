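# Layered validation of the six-table representation.

RECOMMENDED_DESCRIPTIVE_FIELDS <- c(
  "title", "description", "pi_first_name", "pi_last_name",
  "institution", "address", "department"
)

MWTAB_REQUIRED_DESCRIPTIVE_FIELDS <- c(
  "title", "description", "pi_first_name", "pi_last_name", "institution"
)

MWTAB_REQUIRED_PROTOCOL_TYPES <- c("collection", "treatment", "sample_prep", "measurement")

MWTAB_REQUIRED_MEASUREMENT_FIELDS <- c("assignment", "intensity", "entity.id")

#' Base-schema checks
#'
#' Errors: protocol type outside the five-type enumeration; entity type not
#' subject/sample; a record whose embedded `id` field mismatches its key; an
#' empty/missing `id` field; an attribute field (`X%Y`) with no base field
#' `X`. Nuisance warnings: unknown top-level tables; missing recommended
#' descriptive fields on project/study records.
#'
#' @param dataset An [mw_dataset()].
#' @return A findings tibble.
#' @export
validate_base <- function(dataset) {
  out <- empty_findings()
  for (tb in setdiff(names(dataset$tables), dataset_tables())) {
    out <- bind_findings(out, finding(
      "TABLE_UNKNOWN", sprintf("unrecognized table '%s'", tb), table = tb
    ))
  }
  for (tb in names(dataset$tables)) {
    for (id in names(dataset$tables[[tb]])) {
      rec <- dataset$tables[[tb]][[id]]
      embedded <- if (is.null(rec$id)) "" else field_values(rec$id)[1]
      if (!nzchar(embedded)) {
        out <- bind_findings(out, finding(
          "ID_MISSING", "record has an empty or missing 'id' field",
          table = tb, record = id, field = "id"
        ))
      } else if (!identical(embedded, id)) {
        out <- bind_findings(out, finding(
          "ID_MISMATCH",
          sprintf("embedded id '%s' does not reproduce record key '%s'", embedded, id),
          table = tb, record = id, field = "id"
        ))
      }
      for (f in names(rec)) {
        sp <- tryCatch(split_field_attribute(f), error = function(e) NULL)
        if (!is.null(sp) && !is.na(sp$attribute) && !sp$base %in% names(rec)) {
          out <- bind_findings(out, finding(
            "ATTRIBUTE_ORPHANED",
            sprintf("attribute field '%s' has no base field '%s'", f, sp$base),
            table = tb, record = id, field = f
          ))
        }
      }
    }
  }
  for (id in names(ds_table(dataset, "protocol"))) {
    rec <- dataset$tables$protocol[[id]]
    type <- if (is.null(rec$type)) "" else field_values(rec$type)[1]
    if (!type %in% protocol_types()) {
      out <- bind_findings(out, finding(
        "PROTOCOL_TYPE_INVALID",
        sprintf("protocol type '%s' is not one of: %s",
                type, paste(protocol_types(), collapse = ", ")),
        table = "protocol", record = id, field = "type"
      ))
    }
  }
  for (id in names(ds_table(dataset, "entity"))) {
    rec <- dataset$tables$entity[[id]]
    type <- if (is.null(rec$type)) "" else field_values(rec$type)[1]
    if (!type %in% entity_kinds()) {
      out <- bind_findings(out, finding(
        "ENTITY_TYPE_INVALID",
        sprintf("entity type '%s' is not subject or sample", type),
        table = "entity", record = id, field = "type"
      ))
    }
  }
  for (tb in c("project", "study")) {
    for (id in names(ds_table(dataset, tb))) {
      rec <- dataset$tables[[tb]][[id]]
      for (f in setdiff(RECOMMENDED_DESCRIPTIVE_FIELDS, names(rec))) {
        out <- bind_findings(out, finding(
          "FIELD_RECOMMENDED_MISSING",
          sprintf("recommended descriptive field '%s' is missing", f),
          table = tb, record = id, field = f
        ))
      }
    }
  }
  out
}

#' Referential-integrity checks
#'
#' Every field named `<table>.id` must hold ids of existing records in
#' `<table>`; entity `parent_id` must name an existing entity. Each failing
#' id yields one `REF_UNRESOLVED` finding.
#'
#' @param dataset An [mw_dataset()].
#' @return A findings tibble.
#' @export
validate_references <- function(dataset) {
  out <- empty_findings()
  for (tb in names(dataset$tables)) {
    for (id in names(dataset$tables[[tb]])) {
      rec <- dataset$tables[[tb]][[id]]
      for (f in names(rec)) {
        target <- NULL
        if (grepl("^[^%]+\\.id$", f)) {
          target <- sub("\\.id$", "", f)
        } else if (tb == "entity" && f == "parent_id") {
          target <- "entity"
        }
        if (is.null(target)) next
        if (!target %in% c(dataset_tables(), names(dataset$tables))) next
        known <- names(ds_table(dataset, target))
        for (v in field_values(rec[[f]])) {
          if (!v %in% known) {
            out <- bind_findings(out, finding(
              "REF_UNRESOLVED",
              sprintf("'%s' does not resolve in table '%s'", v, target),
              table = tb, record = id, field = f
            ))
          }
        }
      }
    }
  }
  out
}

#' Subject/sample lineage checks
#'
#' A sample derived from a sample must have a sample_prep-type protocol; a
#' sample derived from a subject must have a collection-type protocol
#' (errors). Subjects should have a treatment-type protocol (warning).
#'
#' @param dataset An [mw_dataset()].
#' @return A findings tibble.
#' @export
validate_inheritance <- function(dataset) {
  out <- empty_findings()
  entities <- ds_table(dataset, "entity")
  for (id in names(entities)) {
    rec <- entities[[id]]
    type <- if (is.null(rec$type)) "" else field_values(rec$type)[1]
    types <- entity_protocol_types(dataset, id)
    if (type == "subject" && !"treatment" %in% types) {
      out <- bind_findings(out, finding(
        "LINEAGE_TREATMENT_RECOMMENDED",
        "subjects should have a treatment type protocol",
        table = "entity", record = id
      ))
    }
    if (type != "sample") next
    parent_id <- if (is.null(rec$parent_id)) "" else field_values(rec$parent_id)[1]
    if (!nzchar(parent_id)) next
    parent <- entities[[parent_id]]
    if (is.null(parent)) next  # dangling parent: validate_references reports it
    ptype <- if (is.null(parent$type)) "" else field_values(parent$type)[1]
    if (ptype == "sample" && !"sample_prep" %in% types) {
      out <- bind_findings(out, finding(
        "LINEAGE_SAMPLEPREP_REQUIRED",
        "a sample derived from a sample must have a sample_prep type protocol",
        table = "entity", record = id
      ))
    }
    if (ptype == "subject" && !"collection" %in% types) {
      out <- bind_findings(out, finding(
        "LINEAGE_COLLECTION_REQUIRED",
        "a sample derived from a subject must have a collection type protocol",
        table = "entity", record = id
      ))
    }
  }
  out
}

#' Factor-consistency checks
#'
#' Every entity possessing a factor's controlled field must hold one of the
#' factor's allowed values (`FACTOR_VALUE_INVALID`); a factor whose field
#' appears on no entity draws a nuisance `FACTOR_UNUSED` warning.
#'
#' @param dataset An [mw_dataset()].
#' @return A findings tibble.
#' @export
validate_factors <- function(dataset) {
  out <- empty_findings()
  entities <- ds_table(dataset, "entity")
  for (fid in names(ds_table(dataset, "factor"))) {
    fac <- dataset$tables$factor[[fid]]
    fname <- if (is.null(fac$field)) "" else field_values(fac$field)[1]
    if (!nzchar(fname)) next
    allowed <- if (is.null(fac$allowed_values)) character(0) else field_values(fac$allowed_values)
    used <- FALSE
    for (id in names(entities)) {
      rec <- entities[[id]]
      if (!fname %in% names(rec)) next
      used <- TRUE
      for (v in field_values(rec[[fname]])) {
        if (length(allowed) > 0L && !v %in% allowed) {
          out <- bind_findings(out, finding(
            "FACTOR_VALUE_INVALID",
            sprintf("value '%s' of field '%s' is not among factor '%s' allowed values (%s)",
                    v, fname, fid, paste(allowed, collapse = ", ")),
            table = "entity", record = id, field = fname
          ))
        }
      }
    }
    if (!used) {
      out <- bind_findings(out, finding(
        "FACTOR_UNUSED",
        sprintf("factor field '%s' appears on no entity", fname),
        table = "factor", record = fid
      ))
    }
  }
  out
}

#' Protocol-dependent-schema checks
#'
#' Dataset protocols found in the compiled PD schema must carry all effective
#' required fields (`PDS_FIELD_MISSING`), a matching type
#' (`PDS_TYPE_MISMATCH`) and allowed values where declared
#' (`PDS_VALUE_INVALID`). Protocols absent from the schema draw a nuisance
#' `PDS_UNKNOWN_PROTOCOL` warning.
#'
#' @param dataset An [mw_dataset()].
#' @param pds A compiled PD schema ([compile_pd_schema()]).
#' @return A findings tibble.
#' @export
validate_pds <- function(dataset, pds) {
  out <- empty_findings()
  for (id in names(ds_table(dataset, "protocol"))) {
    rec <- dataset$tables$protocol[[id]]
    eff <- pds[[id]]
    if (is.null(eff)) {
      out <- bind_findings(out, finding(
        "PDS_UNKNOWN_PROTOCOL",
        sprintf("protocol '%s' is not described by the PD schema", id),
        table = "protocol", record = id
      ))
      next
    }
    for (f in setdiff(eff$required_fields, names(rec))) {
      out <- bind_findings(out, finding(
        "PDS_FIELD_MISSING",
        sprintf("protocol '%s' is missing required field '%s'", id, f),
        table = "protocol", record = id, field = f
      ))
    }
    type <- if (is.null(rec$type)) "" else field_values(rec$type)[1]
    if (!identical(type, eff$type)) {
      out <- bind_findings(out, finding(
        "PDS_TYPE_MISMATCH",
        sprintf("protocol '%s' has type '%s' but the PD schema requires '%s'",
                id, type, eff$type),
        table = "protocol", record = id, field = "type"
      ))
    }
    for (f in names(eff$allowed_values)) {
      if (!f %in% names(rec)) next
      for (v in field_values(rec[[f]])) {
        if (!v %in% eff$allowed_values[[f]]) {
          out <- bind_findings(out, finding(
            "PDS_VALUE_INVALID",
            sprintf("protocol '%s' field '%s' value '%s' is not allowed (%s)",
                    id, f, v, paste(eff$allowed_values[[f]], collapse = ", ")),
            table = "protocol", record = id, field = f
          ))
        }
      }
    }
  }
  out
}

#' mwTab conversion-readiness checks
#'
#' Confirms the content the mwTab writer needs is present: a project and a
#' study carrying title, description, PI first/last name and institution; at
#' least one protocol of each of the collection, treatment, sample_prep and
#' measurement types; at least one sample entity and one measurement; and
#' measurement records carrying an assignment, a per-sample intensity and an
#' entity reference.
#'
#' @param dataset An [mw_dataset()].
#' @param machine_type One of ms, nmr, nmr_binned (reserved; the checks are
#'   currently common to all three).
#' @return A findings tibble.
#' @export
validate_format_mwtab <- function(dataset, machine_type = "ms") {
  out <- empty_findings()
  for (tb in c("project", "study")) {
    recs <- ds_table(dataset, tb)
    if (length(recs) == 0L) {
      out <- bind_findings(out, finding(
        "MWTAB_MISSING_RECORD", sprintf("no %s record", tb), table = tb
      ))
      next
    }
    rec <- recs[[1]]
    for (f in setdiff(MWTAB_REQUIRED_DESCRIPTIVE_FIELDS, names(rec))) {
      out <- bind_findings(out, finding(
        "MWTAB_MISSING_FIELD",
        sprintf("%s field '%s' is required for mwTab conversion", tb, f),
        table = tb, record = names(recs)[1], field = f
      ))
    }
  }
  prot_types <- unique(unlist(lapply(ds_table(dataset, "protocol"), function(r) {
    if (is.null(r$type)) character(0) else field_values(r$type)[1]
  })))
  for (ty in setdiff(MWTAB_REQUIRED_PROTOCOL_TYPES, prot_types)) {
    out <- bind_findings(out, finding(
      "MWTAB_MISSING_PROTOCOL",
      sprintf("no protocol of type '%s'", ty), table = "protocol"
    ))
  }
  sample_ids <- names(Filter(
    function(r) !is.null(r$type) && field_values(r$type)[1] == "sample",
    ds_table(dataset, "entity")
  ))
  if (length(sample_ids) == 0L) {
    out <- bind_findings(out, finding(
      "MWTAB_MISSING_RECORD", "no sample entity", table = "entity"
    ))
  }
  meas <- ds_table(dataset, "measurement")
  if (length(meas) == 0L) {
    out <- bind_findings(out, finding(
      "MWTAB_MISSING_RECORD", "no measurement record", table = "measurement"
    ))
  }
  for (id in names(meas)) {
    for (f in setdiff(MWTAB_REQUIRED_MEASUREMENT_FIELDS, names(meas[[id]]))) {
      out <- bind_findings(out, finding(
        "MWTAB_MISSING_FIELD",
        sprintf("measurement field '%s' is required for the data matrix", f),
        table = "measurement", record = id, field = f
      ))
    }
  }
  out
}

#' Validate a dataset
#'
#' Runs the base-schema, referential, lineage and factor checks, plus the
#' PD-schema checks when a schema is supplied and the mwTab readiness checks
#' when `format = "mwtab"`, then filters the findings at the requested
#' silencing level.
#'
#' @param dataset An [mw_dataset()].
#' @param pds Optional PD schema: a path, a raw (`mw_pds`) or compiled
#'   (`mw_compiled_pds`) schema.
#' @param format `NULL` or `"mwtab"`.
#' @param machine_type Passed to [validate_format_mwtab()].
#' @param silent Filtering level, see [filter_findings()].
#' @return An `mw_validation_report`.
#' @export
validate_dataset <- function(dataset, pds = NULL, format = NULL,
                             machine_type = "ms", silent = "none") {
  if (is.character(pds)) pds <- read_pd_schema(pds)
  if (inherits(pds, "mw_pds")) pds <- compile_pd_schema(pds)
  findings <- bind_findings(
    validate_base(dataset),
    validate_references(dataset),
    validate_inheritance(dataset),
    validate_factors(dataset),
    if (!is.null(pds)) validate_pds(dataset, pds),
    if (identical(format, "mwtab")) validate_format_mwtab(dataset, machine_type)
  )
  filter_findings(findings, silent)
}
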