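#' Nucleotide mismatch fraction between equal-length strings
#'
#' The clonal-lineage predicate compares CDR3 segments of identical length,
#' so only substitutions are possible and the mismatch fraction is the
#' Hamming distance divided by the length. `N` against any other base counts
#' as a mismatch (conservative); `N` against `N` matches.
#'
#' @param a,b nucleotide strings of equal length (>= 1).
#' @return Fraction of differing positions, in \[0, 1\].
#' @examples
#' hamming_fraction("ACGTACGTACGTACG", "ACGAACGAACGTACG") # 2/15
#' @export
hamming_fraction <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort(sprintf("hamming_fraction needs equal lengths (got %d and %d); group by CDR3 length first",
                  nchar(a), nchar(b)))
  }
  if (nchar(a) < 1) abort("hamming_fraction needs length >= 1")
  av <- charToRaw(a)
  bv <- charToRaw(b)
  sum(av != bv) / length(av)
}

#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (substitution, insertion, deletion),
#' used to attach heavy chains to the nearest single-cell reference when a
#' lineage splits over divergent light chains.
#'
#' @param a,b character strings.
#' @return Integer edit distance.
#' @examples
#' levenshtein_distance("", "ACG")      # 3
#' levenshtein_distance("ACGT", "AGT")  # 1
#' @export
levenshtein_distance <- function(a, b) {
  as.integer(adist(a, b)[1, 1])
}

#' Somatic hypermutation percentage of a V segment
#'
#' Mismatch percentage between an observed V sequence and its germline
#' allele over a pre-aligned region of equal length. Positions where either
#' sequence carries `N` are excluded from both numerator and denominator
#' (the standard repertoire convention, since `N` reflects sequencing
#' uncertainty, not mutation).
#'
#' @param v_sequence observed V-segment nucleotides.
#' @param germline_v germline V allele nucleotides, same length.
#' @return Percentage of mismatched comparable positions (0-100).
#' @examples
#' shm_percent(paste(rep("A", 200), collapse = ""),
#'             paste(c(rep("A", 198), "G", "G"), collapse = "")) # 1.0
#' @export
shm_percent <- function(v_sequence, germline_v) {
  if (nchar(v_sequence) != nchar(germline_v)) {
    abort("shm_percent needs pre-aligned sequences of equal length")
  }
  av <- strsplit(v_sequence, "")[[1]]
  bv <- strsplit(germline_v, "")[[1]]
  keep <- av != "N" & bv != "N"
  if (!any(keep)) abort("no comparable positions (all N)")
  100 * sum(av[keep] != bv[keep]) / sum(keep)
}
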