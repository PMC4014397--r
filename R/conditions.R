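#' Canonicalize a set of condition labels
#'
#' A growth condition is identified by the set of media supplements added to
#' the base medium (e.g. `c("A","B")` for the pair A+B). Sets are stored in a
#' canonical form -- unique labels, sorted -- so that `{B,A}` and `{A,B}`
#' compare equal. An empty set denotes the base medium alone.
#'
#' @param labels character vector of supplement labels, or a single string
#'   with labels joined by `"+"` (e.g. `"A+B+C"`).
#' @return character vector of unique labels in sorted order (possibly empty).
#' @examples
#' condition_set(c("B", "A"))   # "A" "B"
#' condition_set("C+A")         # "A" "C"
#' @export
condition_set <- function(labels) {
  if (is.null(labels)) return(character(0))
  stopifnot(is.character(labels))
  if (length(labels) == 1L && grepl("+", labels, fixed = TRUE))
    labels <- strsplit(labels, "+", fixed = TRUE)[[1]]
  labels <- labels[nzchar(labels)]
  sort(unique(labels))
}

#' Format a condition set as a "+"-joined key
#'
#' @param labels character vector of supplement labels.
#' @return single string, labels sorted and joined by `"+"`; `""` for the
#'   base medium.
#' @export
condition_key <- function(labels) {
  paste(condition_set(labels), collapse = "+")
}

#' All condition combinations of a label set
#'
#' Enumerates every non-empty subset of `labels` up to size `max_size`, in
#' canonical order (by size, then lexicographically). With the four default
#' labels this yields the 15 combinations: 4 singles, 6 pairs, 4 triplets and
#' the quadruplet.
#'
#' @param labels character vector of single-supplement labels.
#' @param max_size largest subset size to include (default: all).
#' @return list of character vectors (canonical condition sets).
#' @export
condition_combinations <- function(labels, max_size = length(labels)) {
  labels <- condition_set(labels)
  out <- list()
  for (k in seq_len(min(max_size, length(labels)))) {
    cmb <- utils::combn(labels, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}
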