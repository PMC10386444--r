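# Layered validation: base schema, references, lineage, factors, PD schema,
# mwTab readiness, filtering.

test_that("PD-schema compilation walks inheritance chains", {
  raw <- structure(list(
    MS = new_pds_entry(type = "measurement", required_fields = "description"),
    `IC-FTMS` = new_pds_entry(parent = "MS", required_fields = "instrument")
  ), class = "mw_pds")
  eff <- compile_pd_schema(raw)
  expect_equal(eff$`IC-FTMS`$type, "measurement")
  expect_equal(eff$`IC-FTMS`$required_fields, c("description", "instrument"))
  expect_equal(eff$MS$required_fields, "description")  # root: effective == raw
})

test_that("PD-schema cycles and untyped protocols are errors", {
  loop <- structure(list(
    A = new_pds_entry(parent = "B", type = "storage"),
    B = new_pds_entry(parent = "A")
  ), class = "mw_pds")
  expect_error(compile_pd_schema(loop), class = "mwd_pds_cycle_error")
  untyped <- structure(list(A = new_pds_entry()), class = "mw_pds")
  expect_error(compile_pd_schema(untyped), class = "mwd_pds_untyped_error")
})

test_that("child effective requirements are a superset of the parent's", {
  # property over random forests (<= 20 nodes)
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    names_all <- sprintf("p%02d", seq_len(n))
    raw <- list()
    for (i in seq_len(n)) {
      parent <- if (i == 1L || stats::runif(1) < 0.3) NA_character_ else
        names_all[sample(seq_len(i - 1L), 1)]
      raw[[names_all[i]]] <- new_pds_entry(
        parent = parent,
        type = if (is.na(parent) || stats::runif(1) < 0.5) sample(protocol_types(), 1) else NA_character_,
        required_fields = sample(letters, sample(0:4, 1))
      )
    }
    eff <- compile_pd_schema(structure(raw, class = "mw_pds"))
    for (nm in names_all) {
      parent <- raw[[nm]]$parent
      if (is.na(parent)) next
      expect_true(all(eff[[parent]]$required_fields %in% eff[[nm]]$required_fields))
    }
  }
})

test_that("tabular and JSON PD schemas compile to the same requirements", {
  tab <- read_pd_schema(fixture_pds_path())
  json_path <- withr::local_tempfile(fileext = ".json")
  write_pd_schema_json(tab, json_path)
  expect_equal(compile_pd_schema(read_pd_schema(json_path)), compile_pd_schema(tab))
  eff <- compile_pd_schema(tab)
  expect_equal(eff$`IC-FTMS`$type, "measurement")
  expect_setequal(eff$`IC-FTMS`$required_fields,
                  c("description", "chromatography_type", "instrument"))
  expect_equal(eff$`IC-FTMS`$allowed_values$chromatography_type,
               c("Targeted IC", "HILIC"))
})

test_that("base checks catch type, id and attribute violations", {
  ds <- tiny_dataset(
    protocol = list(pX = list(type = "extraction")),
    entity = list(e1 = list(type = "specimen", `height%unit` = "cm"))
  )
  f <- validate_base(ds)
  expect_codes(f, c("PROTOCOL_TYPE_INVALID", "ENTITY_TYPE_INVALID", "ATTRIBUTE_ORPHANED"))
  ds2 <- tiny_dataset(project = list(p1 = list(title = "t")))
  ds2$tables$project$p1$id <- "wrong"
  f2 <- validate_base(ds2)
  expect_true("ID_MISMATCH" %in% f2$code)
  ds3 <- mw_dataset(list(weird = list(r1 = list(id = "r1"))))
  expect_true("TABLE_UNKNOWN" %in% validate_base(ds3)$code)
})

test_that("missing recommended descriptive fields are nuisance warnings", {
  ds <- tiny_dataset(study = list(s1 = list(title = "t")))
  f <- validate_base(ds)
  miss <- f[f$code == "FIELD_RECOMMENDED_MISSING", ]
  expect_true("description" %in% miss$field)
  expect_true(all(miss$nuisance))
  expect_true(all(miss$severity == "warning"))
})

test_that("reference checks resolve <table>.id and parent_id fields", {
  ds <- tiny_dataset(
    protocol = list(p1 = list(type = "storage"), p2 = list(type = "treatment"),
                    p3 = list(type = "collection")),
    entity = list(e1 = list(type = "sample",
                            `protocol.id` = I(c("p1", "ghost", "p3")),
                            parent_id = "nobody")),
    measurement = list(m1 = list(`entity.id` = "colon_1", assignment = "a",
                                 intensity = "1"))
  )
  f <- validate_references(ds)
  expect_equal(sum(f$code == "REF_UNRESOLVED"), 3L)
  expect_true(any(grepl("ghost", f$message)))   # exactly the unknown id is named
  expect_true(any(grepl("colon_1", f$message)))
  clean <- clean_dataset()
  expect_equal(nrow(validate_references(clean)), 0L)
})

test_that("lineage rules tie parentage to required protocol types", {
  base <- list(
    protocol = list(prep = list(type = "sample_prep"), col = list(type = "collection"),
                    sto = list(type = "storage"))
  )
  # sample from sample without sample_prep
  ds <- tiny_dataset(
    protocol = base$protocol,
    entity = list(
      mother = list(type = "sample", `protocol.id` = I("prep")),
      child = list(type = "sample", parent_id = "mother", `protocol.id` = I("sto"))
    )
  )
  expect_codes(validate_inheritance(ds), "LINEAGE_SAMPLEPREP_REQUIRED")
  # sample from subject without collection
  ds2 <- tiny_dataset(
    protocol = base$protocol,
    entity = list(
      subj = list(type = "subject"),
      child = list(type = "sample", parent_id = "subj", `protocol.id` = I("prep"))
    )
  )
  f2 <- validate_inheritance(ds2)
  expect_true("LINEAGE_COLLECTION_REQUIRED" %in% f2$code)
  # subject without treatment: warning only
  ds3 <- tiny_dataset(entity = list(subj = list(type = "subject")))
  f3 <- validate_inheritance(ds3)
  expect_equal(f3$code, "LINEAGE_TREATMENT_RECOMMENDED")
  expect_equal(f3$severity, "warning")
  # compliant sample<-subject draws no finding
  ds4 <- tiny_dataset(
    protocol = c(base$protocol, list(trt = list(type = "treatment"))),
    entity = list(
      subj = list(type = "subject", `protocol.id` = I("trt")),
      child = list(type = "sample", parent_id = "subj", `protocol.id` = I("col"))
    )
  )
  expect_equal(nrow(validate_inheritance(ds4)), 0L)
})

test_that("factor values are constrained to the allowed set", {
  ds <- tiny_dataset(
    factor = list(time = list(field = "time_point", allowed_values = I(c("0", "7")))),
    entity = list(e1 = list(type = "subject", time_point = "7"),
                  e2 = list(type = "subject", time_point = "14"))
  )
  f <- validate_factors(ds)
  expect_equal(f$code, "FACTOR_VALUE_INVALID")
  expect_equal(f$record, "e2")
  unused <- tiny_dataset(
    factor = list(dose = list(field = "dose", allowed_values = I("low"))),
    entity = list(e1 = list(type = "subject"))
  )
  fu <- validate_factors(unused)
  expect_equal(fu$code, "FACTOR_UNUSED")
  expect_true(fu$nuisance)
})

test_that("PD-schema enforcement covers fields, types and allowed values", {
  pds <- compile_pd_schema(read_pd_schema(fixture_pds_path()))
  ds <- clean_dataset()
  expect_equal(nrow(validate_pds(ds, pds)[validate_pds(ds, pds)$severity == "error", ]), 0L)
  broken <- ds
  broken$tables$protocol$`IC-FTMS`$instrument <- NULL
  f <- validate_pds(broken, pds)
  expect_equal(f$code[f$severity == "error"], "PDS_FIELD_MISSING")
  unknown <- validate_pds(ds, pds)
  expect_true(all(unknown$code %in% "PDS_UNKNOWN_PROTOCOL"))
  expect_true(all(unknown$nuisance))
})

test_that("mwTab readiness requires the deposition's minimum content", {
  ds <- clean_dataset()
  expect_equal(nrow(validate_format_mwtab(ds)), 0L)
  no_col <- ds
  no_col$tables$protocol$tissue_collection$type <- "storage"
  expect_true("MWTAB_MISSING_PROTOCOL" %in% validate_format_mwtab(no_col)$code)
  no_inst <- ds
  no_inst$tables$project$project_1$institution <- NULL
  f <- validate_format_mwtab(no_inst)
  expect_equal(f$code, "MWTAB_MISSING_FIELD")
  expect_equal(f$field, "institution")
})

test_that("filtering never drops errors and respects the silencing levels", {
  findings <- bind_findings(
    finding("REF_UNRESOLVED", "e1"),
    finding("REF_UNRESOLVED", "e2"),
    finding("FACTOR_UNUSED", "w1"),
    finding("FACTOR_UNUSED", "w2"),
    finding("FACTOR_UNUSED", "w3"),
    finding("LINEAGE_TREATMENT_RECOMMENDED", "w4")
  )
  expect_equal(nrow(filter_findings(findings, "none")$findings), 6L)
  nuis <- filter_findings(findings, "nuisance")
  expect_equal(nrow(nuis$findings), 3L)  # 2 errors + 1 non-nuisance warning
  expect_equal(nuis$n_errors, 2L)
  allq <- filter_findings(findings, "all")
  expect_equal(nrow(allq$findings), 2L)
  expect_true(all(allq$findings$severity == "error"))
})

test_that("the clean fixture validates with zero findings at nuisance level", {
  rep <- validate_dataset(clean_dataset(), pds = fixture_pds_path(),
                          format = "mwtab", silent = "nuisance")
  expect_equal(nrow(rep$findings), 0L)
  expect_equal(glance(rep)$n_errors, 0L)
})

test_that("every error code is triggered exactly by its fault fixture", {
  pds <- fixture_pds_path()
  for (code in fault_codes()) {
    path <- suppressWarnings(generate_faulty(fixture_params(), code))
    rep <- validate_dataset(read_dataset_json(path), pds = pds, format = "mwtab")
    errs <- unique(rep$findings$code[rep$findings$severity == "error"])
    expect_identical(errs, code, label = sprintf("fault %s yielded [%s]", code,
                                                 paste(errs, collapse = ", ")))
  }
})

test_that("adding a record never removes findings about other records", {
  base <- tiny_dataset(
    protocol = list(pX = list(type = "extraction")),
    entity = list(e1 = list(type = "sample", `protocol.id` = I("ghost")))
  )
  before <- bind_findings(validate_base(base), validate_references(base))
  grown <- base
  grown$tables$entity$e2 <- list(id = "e2", type = "specimen")
  after <- bind_findings(validate_base(grown), validate_references(grown))
  key <- function(f) paste(f$code, f$table, f$record, f$field)
  expect_true(all(key(before) %in% key(after)))
})
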