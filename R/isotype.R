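#' Assign an isotype from a constant-region sequence
#'
#' The expressed constant gene determines the antibody class. Each observed
#' constant-region fragment is compared to every reference by ungapped
#' prefix alignment: identity is the fraction of matching positions over
#' the overlap (the shorter of the two prefixes). The best-scoring
#' reference wins; if the best identity falls below `min_score`, or the
#' fragment is empty, the call is `"unknown"`.
#'
#' @param c_sequence observed constant-region nucleotides (may be `NA`).
#' @param c_refs named character vector mapping isotype (e.g. `"IgA"`,
#'   `"IgG1"`) to its constant-region reference sequence.
#' @param min_score minimum identity for a confident call (default 0.90).
#' @return Isotype name, or `"unknown"`.
#' @examples
#' refs <- c(IgA = "GCATCCCCGACCAGCCCC", IgM = "GGGAGTGCATCCGCCCCA")
#' assign_isotype("GCATCCCCGACCAGCCCC", refs)
#' @export
assign_isotype <- function(c_sequence, c_refs, min_score = 0.90) {
  if (!length(c_refs)) abort("empty constant-region reference set")
  if (is.na(c_sequence) || !nzchar(c_sequence)) return("unknown")
  scores <- vapply(c_refs, function(ref) {
    L <- min(nchar(c_sequence), nchar(ref))
    if (L == 0) return(0)
    a <- charToRaw(substr(c_sequence, 1, L))
    b <- charToRaw(substr(ref, 1, L))
    sum(a == b) / L
  }, numeric(1))
  best <- which.max(scores)
  if (scores[best] < min_score) "unknown" else names(c_refs)[best]
}

#' Assign isotypes across a rearrangement table
#'
#' Vectorised [assign_isotype()]: fills/overwrites an `isotype` column from
#' the `c_sequence` column. Rows without a constant-region fragment become
#' `"unknown"`.
#'
#' @param records rearrangement tibble.
#' @inheritParams assign_isotype
#' @return The tibble with an `isotype` column.
#' @export
assign_isotypes <- function(records, c_refs, min_score = 0.90) {
  records$isotype <- vapply(
    records$c_sequence, assign_isotype, character(1),
    c_refs = c_refs, min_score = min_score, USE.NAMES = FALSE
  )
  records
}
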