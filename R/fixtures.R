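# Self-contained toy fixtures: a small IC-FTMS-style mouse colon study
# (subjects -> samples -> per-metabolite measurements) fabricated entirely in
# code, so every pipeline stage is exercisable with no downloads and no
# binary files in the repository.

#' Fixture parameters
#'
#' Generation is a pure function of these parameters plus the seed: the same
#' values always produce byte-identical files.
#'
#' @param n_subjects Number of subject entities (>= 1).
#' @param n_samples_per_subject Samples collected per subject (>= 1).
#' @param n_metabolites Metabolites measured per sample (>= 1).
#' @param factor_levels Levels of the single experimental factor (time point,
#'   in days); subjects are assigned levels round-robin.
#' @param seed Integer seed driving the simulated intensities.
#' @return A list of class `mw_fixture_params`.
#' @export
fixture_params <- function(n_subjects = 2L, n_samples_per_subject = 2L,
                           n_metabolites = 3L, factor_levels = c("0", "7"),
                           seed = 1L) {
  stopifnot(n_subjects >= 1L, n_samples_per_subject >= 1L, n_metabolites >= 1L,
            length(factor_levels) >= 1L)
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_samples_per_subject = as.integer(n_samples_per_subject),
         n_metabolites = as.integer(n_metabolites),
         factor_levels = as.character(factor_levels),
         seed = as.integer(seed)),
    class = "mw_fixture_params"
  )
}

fixture_metabolites <- function(n) {
  base <- c("glucose", "lactate", "succinate", "citrate", "fumarate", "malate")
  formulas <- c("C6H12O6", "C3H6O3", "C4H6O4", "C6H8O7", "C4H4O4", "C4H6O5")
  if (n <= length(base)) {
    list(names = base[seq_len(n)], formulas = formulas[seq_len(n)])
  } else {
    extra <- n - length(base)
    list(
      names = c(base, sprintf("metabolite_%02d", seq_len(extra))),
      formulas = c(formulas, rep("C0H0", extra))
    )
  }
}

pad_rows <- function(rows) {
  w <- max(vapply(rows, length, integer(1)))
  do.call(rbind, lapply(rows, function(r) c(r, rep("", w - length(r)))))
}

metadata_export_cells <- function(params) {
  contact <- function(tb, id, title, desc) {
    list(
      c("#tags", paste0("#", tb, ".id"), paste0("#", tb, ".title"),
        paste0("#", tb, ".description"), paste0("#", tb, ".pi_first_name"),
        paste0("#", tb, ".pi_last_name"), paste0("#", tb, ".institution"),
        paste0("#", tb, ".address"), paste0("#", tb, ".department"),
        paste0("#", tb, ".pi_email"),
        if (tb == "study") "#study.project.id=project_1"),
      c("", id, title, desc, "Pat", "Investigator", "Example University",
        "123 Example Street, Lexington KY", "Biochemistry", "pi@example.org")
    )
  }
  protocols <- list(
    c("#tags", "#protocol.id", "#protocol.type", "#protocol.description",
      "#protocol.instrument", "#protocol.instrument_type",
      "#protocol.chromatography_type", "#protocol.ms_type", "#protocol.ion_mode"),
    c("", "time_treatment", "treatment",
      "Mice were maintained on a standard diet for 0 or 7 days before collection"),
    c("", "tissue_collection", "collection",
      "Colon tissue was collected immediately after euthanasia and flash frozen"),
    c("", "polar_extraction", "sample_prep",
      "Polar metabolites were extracted from pulverized frozen tissue"),
    c("", "IC-FTMS", "measurement",
      "Targeted ion chromatography Fourier transform mass spectrometry acquisition",
      "Orbitrap Fusion", "IC-FTMS", "Targeted IC", "ESI", "NEGATIVE"),
    c("", "freezer_storage", "storage",
      "Tissue aliquots stored at -80C until extraction")
  )
  subjects <- list(c(
    "#tags", "#entity.id", "#entity.type=subject", "#entity.species",
    "#entity.subject_type", "#entity.taxonomy_id", "#entity.time_point",
    "*#entity.protocol.id"
  ))
  lv <- params$factor_levels
  for (i in seq_len(params$n_subjects)) {
    subjects[[length(subjects) + 1L]] <- c(
      "", sprintf("subject_%d", i), "x", "Mus musculus", "Mammal", "10090",
      lv[((i - 1L) %% length(lv)) + 1L], "time_treatment"
    )
  }
  samples <- list(c(
    "#tags", "#entity.id", "#entity.type=sample", "#entity.parent_id",
    "*#entity.protocol.id", "#entity.weight", "#entity.weight%unit"
  ))
  for (i in seq_len(params$n_subjects)) {
    for (j in seq_len(params$n_samples_per_subject)) {
      samples[[length(samples) + 1L]] <- c(
        "", sprintf("sample_%d_%d", i, j), "x", sprintf("subject_%d", i),
        "tissue_collection,polar_extraction,freezer_storage",
        render_number(20 + 3 * i + j), "mg"
      )
    }
  }
  factors <- list(
    c("#tags", "#factor.id", "#factor.field", "*#factor.allowed_values",
      "#factor.units"),
    c("", "time_point", "time_point", paste(lv, collapse = ","), "day")
  )
  blank <- list("")
  pad_rows(c(
    contact("project", "project_1", "Mouse colon IC-FTMS study",
            "Toy targeted IC-FTMS metabolomics study of mouse colon tissue"),
    blank,
    contact("study", "study_1", "Colon tissue time course",
            "Colon tissue collected at two time points after diet start"),
    blank, protocols, blank, subjects, blank, samples, blank, factors
  ))
}

measurement_data_cells <- function(params) {
  met <- fixture_metabolites(params$n_metabolites)
  rows <- list(c("Measurement ID", "Sample ID", "Metabolite", "Formula",
                 "Intensity", "Units", "Protocol"))
  # deterministic intensities: one stream, fixed order
  set.seed(params$seed)
  for (i in seq_len(params$n_subjects)) {
    for (j in seq_len(params$n_samples_per_subject)) {
      sid <- sprintf("sample_%d_%d", i, j)
      for (k in seq_len(params$n_metabolites)) {
        intensity <- round(exp(stats::rnorm(1, mean = 12, sd = 1)), 1)
        rows[[length(rows) + 1L]] <- c(
          paste0(met$names[k], "-", sid), sid, met$names[k], met$formulas[k],
          render_number(intensity), "peak area", "old_ICMS"
        )
      }
    }
  }
  pad_rows(rows)
}

automation_cells <- function() {
  pad_rows(list(
    c("header", "tag", "required"),
    c("Measurement ID", "#measurement.id", "true"),
    c("Sample ID", "#measurement.entity.id", "true"),
    c("Metabolite", "#measurement.assignment", "true"),
    c("Formula", "#measurement.formula", "false"),
    c("Intensity", "#measurement.intensity", "true"),
    c("Units", "#measurement.intensity%type", "false"),
    c("Protocol", "*#measurement.protocol.id", "false")
  ))
}

modification_cells <- function() {
  pad_rows(list(
    c("table", "records", "field", "operation", "value", "pattern"),
    c("measurement", ".*", "protocol.id", "regex-substitute", "IC-FTMS", "^old_ICMS$")
  ))
}

#' Generate the fixture workbooks
#'
#' Writes (a) a metadata workbook whose `#export` sheet holds tagged
#' project/study/protocol/entity/factor blocks and (b) a measurement workbook
#' holding an untagged data table plus `#automate` and `#modify` sheets (the
#' modification is a regex-substitute renaming the measurement protocol).
#' CSV fallbacks of every sheet are written alongside the XLSX files.
#'
#' @param params A [fixture_params()] object.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the generated file paths.
#' @export
generate_workbooks <- function(params = fixture_params(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  meta_cells <- metadata_export_cells(params)
  data_cells <- measurement_data_cells(params)
  auto_cells <- automation_cells()
  mod_cells <- modification_cells()

  metadata_xlsx <- file.path(out_dir, "metadata.xlsx")
  measurements_xlsx <- file.path(out_dir, "measurements.xlsx")
  write_xlsx_grids(list("#export" = meta_cells), metadata_xlsx)
  write_xlsx_grids(
    list("data" = data_cells, "#automate" = auto_cells, "#modify" = mod_cells),
    measurements_xlsx
  )
  csvs <- c(
    metadata_export = file.path(out_dir, "metadata_export.csv"),
    measurements_data = file.path(out_dir, "measurements_data.csv"),
    measurements_automate = file.path(out_dir, "measurements_automate.csv"),
    measurements_modify = file.path(out_dir, "measurements_modify.csv")
  )
  write_grid_csv(mw_grid(meta_cells), csvs[["metadata_export"]])
  write_grid_csv(mw_grid(data_cells), csvs[["measurements_data"]])
  write_grid_csv(mw_grid(auto_cells), csvs[["measurements_automate"]])
  write_grid_csv(mw_grid(mod_cells), csvs[["measurements_modify"]])
  c(metadata = metadata_xlsx, measurements = measurements_xlsx, csvs)
}

#' Generate the fixture PD schema
#'
#' Writes a tagged tabular parent_protocol schema with a two-level
#' inheritance chain: a measurement root (`MS`) requiring a description, and
#' an `IC-FTMS` child adding instrument requirements and an allowed-values
#' constraint on the chromatography type.
#'
#' @param out_path Output CSV path.
#' @return `out_path`, invisibly.
#' @export
generate_pds <- function(out_path) {
  cells <- pad_rows(list(
    c("#tags", "#parent_protocol.id", "#parent_protocol.parent_id",
      "#parent_protocol.type", "*#parent_protocol.required_fields",
      "*#parent_protocol.optional_fields",
      "*#parent_protocol.allowed_values%chromatography_type"),
    c("", "MS", "", "measurement", "description",
      "instrument_type,ms_type,ion_mode", ""),
    c("", "IC-FTMS", "MS", "", "chromatography_type,instrument", "", "Targeted IC,HILIC")
  ))
  write_grid_csv(mw_grid(cells), out_path)
  invisible(out_path)
}

#' Extract the clean fixture dataset
#'
#' Generates the workbooks in a scratch directory and runs the full extract
#' step (export tags, automation, modification) over them.
#'
#' @param params A [fixture_params()] object.
#' @param dir Scratch directory (default a fresh temporary directory).
#' @return An [mw_dataset()].
#' @export
fixture_dataset <- function(params = fixture_params(), dir = tempfile("fixture")) {
  paths <- generate_workbooks(params, dir)
  extract_dataset(c(paths[["metadata"]], paths[["measurements"]]))
}

#' Error codes coverable by fault injection
#'
#' @return Character vector of the registry's error codes.
#' @export
fault_codes <- function() {
  FINDING_REGISTRY$code[FINDING_REGISTRY$severity == "error"]
}

inject_fault <- function(dataset, fault_code) {
  t <- dataset$tables
  switch(
    fault_code,
    PROTOCOL_TYPE_INVALID = {
      t$protocol$bogus_protocol <- list(id = "bogus_protocol", type = "extraction",
                                        description = "mistyped protocol")
    },
    ENTITY_TYPE_INVALID = {
      t$entity$specimen_1 <- list(id = "specimen_1", type = "specimen")
    },
    ID_MISMATCH = {
      t$project[[1]]$id <- "not_the_key"
    },
    ID_MISSING = {
      t$study[[1]]$id <- ""
    },
    ATTRIBUTE_ORPHANED = {
      first <- names(t$entity)[1]
      t$entity[[first]][["height%unit"]] <- "cm"
    },
    REF_UNRESOLVED = {
      first <- names(t$measurement)[1]
      t$measurement[[first]][["entity.id"]] <- "no_such_sample"
    },
    LINEAGE_SAMPLEPREP_REQUIRED = {
      parent <- names(Filter(function(r) identical(r$type, "sample"), t$entity))[1]
      t$entity$aliquot_1 <- list(
        id = "aliquot_1", type = "sample", parent_id = parent,
        protocol.id = I("freezer_storage")
      )
    },
    LINEAGE_COLLECTION_REQUIRED = {
      parent <- names(Filter(function(r) identical(r$type, "subject"), t$entity))[1]
      t$entity$swab_1 <- list(
        id = "swab_1", type = "sample", parent_id = parent,
        protocol.id = I("polar_extraction")
      )
    },
    FACTOR_VALUE_INVALID = {
      subj <- names(Filter(function(r) identical(r$type, "subject"), t$entity))[1]
      t$entity[[subj]]$time_point <- "14"
    },
    PDS_FIELD_MISSING = {
      t$protocol[["IC-FTMS"]]$instrument <- NULL
    },
    PDS_TYPE_MISMATCH = {
      t$protocol$MS <- list(id = "MS", type = "storage",
                            description = "mislabelled root protocol")
    },
    PDS_VALUE_INVALID = {
      t$protocol[["IC-FTMS"]]$chromatography_type <- "GC"
    },
    MWTAB_MISSING_PROTOCOL = {
      # a dataset with no collection protocol and no subject-derived samples
      t$protocol$tissue_collection <- NULL
      subjects <- names(Filter(function(r) identical(r$type, "subject"), t$entity))
      t$entity <- t$entity[setdiff(names(t$entity), subjects)]
      for (id in names(t$entity)) {
        t$entity[[id]]$parent_id <- NULL
        t$entity[[id]][["protocol.id"]] <- I(c("polar_extraction", "freezer_storage"))
        t$entity[[id]]$time_point <- t$entity[[id]]$time_point %||% "0"
      }
    },
    MWTAB_MISSING_FIELD = {
      t$project[[1]]$institution <- NULL
    },
    MWTAB_MISSING_RECORD = {
      t$measurement <- structure(list(), names = character(0))
    },
    mwd_abort(sprintf("unknown fault code '%s'", fault_code), "mwd_usage_error")
  )
  mw_dataset(t)
}

#' Generate a fault-injected dataset
#'
#' Starting from the clean fixture dataset, applies one targeted mutation so
#' that full validation (base + references + lineage + factors + PD schema +
#' mwTab readiness) reports exactly the named error code and no other error
#' code.
#'
#' @param params A [fixture_params()] object.
#' @param fault_code One of [fault_codes()].
#' @param out_path Output dataset JSON path (default: a temporary file).
#' @return The path of the written dataset JSON.
#' @export
generate_faulty <- function(params = fixture_params(), fault_code,
                            out_path = tempfile(fileext = ".json")) {
  if (!fault_code %in% fault_codes()) {
    mwd_abort(sprintf("unknown fault code '%s'", fault_code), "mwd_usage_error")
  }
  dataset <- inject_fault(fixture_dataset(params), fault_code)
  write_dataset_json(dataset, out_path)
  out_path
}
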