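#' Read a nucleotide FASTA into a named character vector
#'
#' Multi-line records are joined and upper-cased. Duplicate record names are
#' an error: germline reference sets must identify each allele uniquely.
#'
#' @param path FASTA file path.
#' @return Named character vector, one nucleotide string per record.
#' @examples
#' p <- tempfile(fileext = ".fasta")
#' writeLines(c(">V1", "acgt", "ACGT", ">V2", "GGGG"), p)
#' read_fasta(p)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA not found: ", path))
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    abort(paste0("duplicate FASTA record name(s): ", paste(dup, collapse = ", ")))
  }
  toupper(setNames(as.character(set), nm))
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector of nucleotide strings.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    abort("all sequences must be named")
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}
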