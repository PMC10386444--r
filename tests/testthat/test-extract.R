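# The extract engine: tag grammar, block scanning, export, fuzzy matching,
# automation, modification, merging.

grid_of <- function(...) {
  mw_grid(pad_rows(list(...)))
}
pad_rows <- function(rows) {
  w <- max(vapply(rows, length, integer(1)))
  do.call(rbind, lapply(rows, function(r) c(r, rep("", w - length(r)))))
}

test_that("the tag grammar parses bindings, lists, constants and attributes", {
  t <- parse_tag_cell("#entity.weight%unit")
  expect_equal(t[c("table", "field", "is_list")],
               list(table = "entity", field = "weight%unit", is_list = FALSE))
  t <- parse_tag_cell("*#entity.protocol.id")
  expect_true(t$is_list)
  expect_equal(t$field, "protocol.id")
  t <- parse_tag_cell("#protocol.type=measurement")
  expect_equal(t$constant, "measurement")
  expect_error(parse_tag_cell("entity.id"), class = "mwd_tag_syntax_error")
  expect_error(parse_tag_cell("#entityid"), class = "mwd_tag_syntax_error")
  expect_error(parse_tag_cell("#.id"), class = "mwd_tag_syntax_error")
})

test_that("block scanning finds #tags rows and bounds data correctly", {
  g <- grid_of(
    c("ignored", "prose"),
    c("#tags", "#entity.id", "#entity.type"),
    c("", "s1", "sample"),
    c("", "s2", "sample"),
    c(""),
    c("#tags", "#protocol.id", "#protocol.type"),
    c("", "p1", "storage"),
    c("#end"),
    c("", "below-end", "ignored")
  )
  blocks <- find_tag_blocks(g)
  expect_length(blocks, 2L)
  expect_equal(blocks[[1]]$data_rows, 3:4)
  expect_equal(blocks[[2]]$data_rows, 7L)
})

test_that("blocks need exactly one id tag and at least one data row", {
  g <- grid_of(c("#tags", "#entity.type"), c("", "sample"))
  expect_error(find_tag_blocks(g), class = "mwd_block_structure_error")
  g <- grid_of(c("#tags", "#entity.id", "#protocol.id"), c("", "a", "b"))
  expect_error(find_tag_blocks(g), class = "mwd_block_structure_error")
  g <- grid_of(c("#tags", "#entity.id"), c(""))
  expect_error(find_tag_blocks(g), class = "mwd_empty_block_error")
})

test_that("export builds records keyed by id, with lists and constants", {
  g <- grid_of(
    c("#tags", "#entity.id", "#entity.type", "*#entity.protocol.id",
      "#protocol.type=measurement"),
    c("", "s1", "sample", "chromatography , FTMS", ""),
    c("", "s2", "sample", "", "")
  )
  ds <- export_grid(g)
  expect_equal(ds$tables$entity$s1$type, "sample")
  expect_equal(as.character(ds$tables$entity$s1[["protocol.id"]]),
               c("chromatography", "FTMS"))
  expect_false("protocol.id" %in% names(ds$tables$entity$s2))  # empty cell absent
  # the constant writes into every row's record in its own table
  expect_equal(ds$tables$protocol$s1$type, "measurement")
  expect_equal(ds$tables$protocol$s2$type, "measurement")
})

test_that("empty-id rows are skipped with a warning; duplicate ids error", {
  g <- grid_of(
    c("#tags", "#entity.id", "#entity.type"),
    c("", "", "sample"),
    c("", "s1", "sample")
  )
  expect_warning(ds <- export_grid(g), class = "mwd_empty_id_warning")
  expect_length(ds$tables$entity, 1L)
  g <- grid_of(
    c("#tags", "#entity.id"),
    c("", "s1"),
    c("", "s1")
  )
  expect_error(export_grid(g), class = "mwd_duplicate_record_error")
})

test_that("match_header agrees with a DP oracle and enforces the threshold", {
  expect_equal(match_header("Sample ID", c("Sample ID", "sample_id"))$distance, 0L)
  expect_null(match_header("kitten", "sitting"))          # distance 3 > 2
  expect_equal(lev_dp("kitten", "sitting"), 3L)
  m <- match_header("Smple ID", "Sample ID")
  expect_equal(m$distance, 1L)
  expect_equal(lev_dp("Smple ID", "Sample ID"), 1L)
  expect_error(match_header("ab", c("abc", "abd")), class = "mwd_ambiguous_match_error")
  # property: implementation distance == oracle on random pairs
  set.seed(42)
  for (i in 1:250) {
    a <- random_token(sample(0:12, 1))
    b <- random_token(sample(1:12, 1))
    m <- match_header(a, b, threshold = 100L)
    expect_equal(m$distance, lev_dp(a, b))
  }
})

test_that("automation inserts tags on matched columns, fuzzily", {
  g <- grid_of(
    c("Metabolite", "Intensity"),
    c("glucose", "12"),
    c("lactate", "13")
  )
  dirs <- list(
    automation_directive("Metabolite", "#measurement.id", required = TRUE),
    automation_directive("Intensty", "#measurement.intensity")  # typo, distance 1
  )
  tagged <- apply_automation(g, dirs)
  expect_equal(tagged$cells[1, ], c("#tags", "#measurement.id", "#measurement.intensity"))
  ds <- export_grid(tagged)
  expect_equal(ds$tables$measurement$glucose$intensity, "12")
})

test_that("required automation headers must match; optional ones warn", {
  g <- grid_of(c("Metabolite", "Intensity"), c("glucose", "1"))
  expect_error(
    apply_automation(g, list(automation_directive("RT (min)", "#measurement.rt", required = TRUE))),
    class = "mwd_missing_header_error"
  )
  expect_warning(
    apply_automation(g, list(
      automation_directive("Metabolite", "#measurement.id"),
      automation_directive("Nonexistent column", "#measurement.x")
    )),
    class = "mwd_unmatched_header_warning"
  )
})

test_that("automation soundness: auto-tagged extraction equals hand-tagged", {
  raw <- grid_of(
    c("Metabolite", "Intensity"),
    c("glucose", "12.5"),
    c("lactate", "3")
  )
  hand <- grid_of(
    c("#tags", "#measurement.id", "#measurement.intensity"),
    c("", "glucose", "12.5"),
    c("", "lactate", "3")
  )
  auto <- apply_automation(raw, list(
    automation_directive("Metabolite", "#measurement.id"),
    automation_directive("Intensity", "#measurement.intensity")
  ))
  expect_equal(export_grid(auto)$tables, export_grid(hand)$tables)
})

test_that("modifications: five operations with exact and pattern selectors", {
  ds <- tiny_dataset(
    entity = list(
      s1 = list(unit = "mM", notes = "x", `protocol.id` = I("old_ICMS")),
      s2 = list(unit = "mM", notes = "y"),
      other = list(unit = "mM", notes = "z")
    )
  )
  out <- apply_modifications(ds, list(
    modification_directive("entity", "s1", "unit", "overwrite", "uM"),
    modification_directive("entity", "s.*", "notes", "delete"),
    modification_directive("entity", "s1", "protocol.id", "regex-substitute",
                           value = "", pattern = "^old_"),
    modification_directive("entity", "s2", "unit", "prepend", "~"),
    modification_directive("entity", "s2", "unit", "append", "!")
  ))
  expect_equal(out$tables$entity$s1$unit, "uM")
  expect_false("notes" %in% names(out$tables$entity$s1))
  expect_false("notes" %in% names(out$tables$entity$s2))
  expect_true("notes" %in% names(out$tables$entity$other))
  expect_equal(as.character(out$tables$entity$s1[["protocol.id"]]), "ICMS")
  expect_equal(out$tables$entity$s2$unit, "~mM!")
})

test_that("modification algebra: idempotence, identity and delete-dominance", {
  ds <- tiny_dataset(entity = list(s1 = list(v = "abc")))
  ow <- list(modification_directive("entity", "s1", "v", "overwrite", "zzz"))
  once <- apply_modifications(ds, ow)
  expect_equal(apply_modifications(once, ow)$tables, once$tables)
  noop <- list(modification_directive("entity", "s1", "v", "regex-substitute",
                                      value = "X", pattern = "qqq+"))
  expect_equal(apply_modifications(ds, noop)$tables, ds$tables)
  del_then_op <- suppressWarnings(apply_modifications(ds, list(
    modification_directive("entity", "s1", "v", "delete"),
    modification_directive("entity", "s1", "v", "append", "tail")
  )))
  expect_false("v" %in% names(del_then_op$tables$entity$s1))
})

test_that("zero-match directives warn; bad patterns error", {
  ds <- tiny_dataset(entity = list(s1 = list(v = "a")))
  expect_warning(
    apply_modifications(ds, list(
      modification_directive("entity", "ghost", "v", "overwrite", "b")
    )),
    class = "mwd_no_match_warning"
  )
  expect_error(
    apply_modifications(ds, list(
      modification_directive("entity", "s(", "v", "overwrite", "b")
    )),
    class = "mwd_pattern_error"
  )
})

test_that("delete_entries removes matches and tolerates misses", {
  ds <- tiny_dataset(
    protocol = list(acetone_extraction = list(type = "sample_prep"),
                    keepme = list(type = "storage")),
    entity = list(s1 = list(type = "sample"), s2 = list(type = "sample"))
  )
  out <- delete_entries(ds, list(delete_selector("protocol", "acetone_extraction")))
  expect_equal(names(out$tables$protocol), "keepme")
  expect_warning(
    out2 <- delete_entries(ds, list(delete_selector("protocol", "lipid_.*"))),
    class = "mwd_no_match_warning"
  )
  expect_equal(out2$tables, ds$tables)
  expect_warning(
    delete_entries(ds, list(delete_selector("nonexistent", "x"))),
    class = "mwd_unknown_table_warning"
  )
  all_gone <- delete_entries(ds, list(delete_selector("entity", ".*")))
  expect_length(all_gone$tables$entity, 0L)
})

test_that("merging is a union with later-wins conflict policy", {
  a <- tiny_dataset(entity = list(s1 = list(x = "1")))
  b <- tiny_dataset(entity = list(s1 = list(y = "2"), s2 = list(x = "3")),
                    protocol = list(p1 = list(type = "storage")))
  m <- merge_datasets(a, b)
  expect_equal(m$tables$entity$s1[c("x", "y")], list(x = "1", y = "2"))
  expect_length(m$tables$entity, 2L)
  conflicting <- tiny_dataset(entity = list(s1 = list(x = "9")))
  expect_warning(m2 <- merge_datasets(a, conflicting),
                 class = "mwd_merge_conflict_warning")
  expect_equal(m2$tables$entity$s1$x, "9")
})

test_that("extract is order-invariant for sources with disjoint ids", {
  p <- fixture_paths()
  ab <- extract_dataset(c(p[["metadata"]], p[["measurements"]]))
  ba <- extract_dataset(c(p[["measurements"]], p[["metadata"]]))
  expect_equal(canonicalize_dataset(ab)$tables, canonicalize_dataset(ba)$tables)
})

test_that("a single tagged CSV extracts to a single-table dataset", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#tags,#entity.id,#entity.type", ",s1,sample"), p)
  ds <- extract_dataset(p)
  expect_equal(names(ds$tables), "entity")
})

test_that("save-export output re-extracts to the same records", {
  p <- fixture_paths()
  saved <- withr::local_tempfile(fileext = ".csv")
  with_meas <- extract_dataset(p[["measurements"]], save_export = saved)
  again <- export_grid(read_grid(saved))
  # modification ran on the first pass only; compare pre-modification content
  expect_equal(
    sort(names(again$tables$measurement)),
    sort(names(with_meas$tables$measurement))
  )
  expect_equal(
    again$tables$measurement[["glucose-sample_1_1"]]$intensity,
    with_meas$tables$measurement[["glucose-sample_1_1"]]$intensity
  )
})

test_that("explicit directive files work for automation and modification", {
  p <- fixture_paths()
  auto_json <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    list(header = "Metabolite", tag = "#measurement.id", required = TRUE),
    list(header = "Intensity", tag = "#measurement.intensity")
  ), auto_unbox = TRUE), auto_json)
  raw_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Metabolite,Intensity", "glucose,5"), raw_csv)
  ds <- extract_dataset(raw_csv, automate = auto_json)
  expect_equal(ds$tables$measurement$glucose$intensity, "5")
  mod_json <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    list(table = "measurement", records = "glucose", field = "intensity",
         operation = "overwrite", value = "7")
  ), auto_unbox = TRUE), mod_json)
  ds2 <- extract_dataset(raw_csv, automate = auto_json, modify = mod_json)
  expect_equal(ds2$tables$measurement$glucose$intensity, "7")
  expect_setequal(attr(ds2, "tagging_parts"),
                  c("export", "automation", "modification"))
})
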