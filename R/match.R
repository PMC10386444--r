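#' Fuzzy header matching by Levenshtein distance
#'
#' An exact (case-sensitive) match always wins at distance 0. Otherwise the
#' candidate with minimal Levenshtein edit distance wins, provided that
#' distance does not exceed `threshold` (default 2, i.e. tolerate small typos
#' without letting unrelated headers collide). Two distinct candidates tying
#' at the minimal qualifying distance is ambiguous and raises an error.
#'
#' @param header The header text to place.
#' @param candidates Non-empty character vector of candidate headers.
#' @param threshold Maximum edit distance accepted for a fuzzy match.
#' @return `NULL` if nothing qualifies, else a list with `candidate`,
#'   `distance` and `index` (first position of the winner in `candidates`).
#' @export
match_header <- function(header, candidates, threshold = 2L) {
  stopifnot(is.character(header), length(header) == 1L, length(candidates) > 0L)
  hit <- which(candidates == header)
  if (length(hit) > 0L) {
    return(list(candidate = header, distance = 0L, index = hit[1]))
  }
  dists <- utils::adist(header, candidates)[1, ]
  dmin <- min(dists)
  if (dmin > threshold) return(NULL)
  winners <- unique(candidates[dists == dmin])
  if (length(winners) > 1L) {
    mwd_abort(
      sprintf(
        "ambiguous match for '%s': %s all at distance %d",
        header, paste(sQuote(winners), collapse = ", "), dmin
      ),
      "mwd_ambiguous_match_error"
    )
  }
  idx <- which(candidates == winners)[1]
  list(candidate = winners, distance = as.integer(dmin), index = idx)
}
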