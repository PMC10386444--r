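#' @importFrom rlang abort warn %||%
NULL

# Condition helpers: every user-facing failure carries a stable condition class
# ("mwd_<kind>_error") so callers and tests can branch on the kind, not the text.
mwd_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "mwd_error"), ...)
}

mwd_warn <- function(message, class = "mwd_warning") {
  rlang::warn(message, class = class)
}

#' Render a number as text
#'
#' Numeric values entering the text-only data model are rendered with a single
#' rule: integer-valued numbers carry no decimal point; other numbers use the
#' shortest decimal representation that survives a text -> double round trip.
#'
#' @param x A numeric vector.
#' @return A character vector, one rendered value per element.
#' @examples
#' render_number(c(2, 2.5, 1/3))
#' @export
render_number <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    if (is.finite(v) && v == floor(v) && abs(v) < 2^53) {
      return(sprintf("%.0f", v))
    }
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g", flag = "#")
      s <- sub("\\.$", "", s)
      if (as.numeric(s) == v) return(s)
    }
    as.character(v)
  }, character(1))
}

# Text normalisation for cells: NA -> "", everything else as.character.
cell_text <- function(x) {
  out <- as.character(x)
  out[is.na(out)] <- ""
  out
}

is_blank <- function(x) !nzchar(trimws(x))
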