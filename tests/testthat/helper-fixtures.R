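# Shared fixtures (generated once per test run) and independent oracles.

the <- new.env(parent = emptyenv())

fixture_paths <- function() {
  if (is.null(the$paths)) {
    dir <- file.path(tempdir(), "mwdeposit-fixtures")
    the$paths <- generate_workbooks(fixture_params(), dir)
    the$pds <- generate_pds(file.path(dir, "pd_schema.csv"))
  }
  the$paths
}

fixture_pds_path <- function() {
  fixture_paths()
  the$pds
}

clean_dataset <- function() {
  if (is.null(the$dataset)) {
    p <- fixture_paths()
    the$dataset <- extract_dataset(c(p[["metadata"]], p[["measurements"]]))
  }
  the$dataset
}

# Independent Levenshtein oracle: textbook dynamic programming over the full
# (n+1) x (m+1) table, no shortcuts shared with the implementation under test.
lev_dp <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  n <- length(sa)
  m <- length(sb)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (sa[i] == sb[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(
        d[i, j + 1L] + 1L,
        d[i + 1L, j] + 1L,
        d[i, j] + cost
      )
    }
  }
  d[n + 1L, m + 1L]
}

random_token <- function(len) {
  paste(sample(c(letters[1:6], " ", "_"), len, replace = TRUE), collapse = "")
}

# build a tiny in-memory dataset from a compact spec list
tiny_dataset <- function(...) {
  tables <- list(...)
  for (tb in names(tables)) {
    for (id in names(tables[[tb]])) {
      tables[[tb]][[id]]$id <- tables[[tb]][[id]]$id %||% id
    }
  }
  mw_dataset(tables)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

expect_codes <- function(findings, codes) {
  expect_setequal(unique(findings$code), codes)
}
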