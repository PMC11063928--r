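#' AIRR rearrangement tables
#'
#' Readers and writers for the tab-separated rearrangement dialect emitted by
#' upstream V(D)J annotators (one row per annotated chain). Tables are plain
#' tibbles so they compose with dplyr verbs; the columns follow the AIRR
#' Rearrangement convention: tab-separated, UTF-8, header row, empty string
#' means missing.
#'
#' Required columns: `sequence_id`, `locus` (IGH/IGK/IGL), `v_call`,
#' `j_call`, `cdr3` (nucleotides). Optional columns and their defaults:
#' `cell_id` (`NA`; bulk reads carry none), `c_call` (`NA`), `c_sequence`
#' (constant-region nucleotides, `NA`), `tissue` (`NA`), `source`
#' (inferred: rows with a `cell_id` are `single_cell`, others `bulk`),
#' `duplicate_count` (1), `v_identity` (fraction in \[0,1\], `NA`),
#' `v_sequence` (`NA`), `sequence` (`NA`).
#'
#' @param path file path of a tab-separated rearrangement table.
#' @return A tibble with the columns above, one row per rearrangement.
#' @seealso [write_airr()]
#' @examples
#' tab <- tibble::tibble(
#'   sequence_id = c("s1", "s2"), locus = "IGH",
#'   v_call = "IGHV1-1*01", j_call = "IGHJ4*01",
#'   cdr3 = c("TGTGCGAGA", "TGTGCGAGG"), cell_id = c("c1", NA)
#' )
#' p <- tempfile(fileext = ".tsv")
#' write_airr(tab, p)
#' read_airr(p)$source
#' @export
read_airr <- function(path) {
  if (!file.exists(path)) abort(paste0("AIRR table not found: ", path))
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  tab[tab == ""] <- NA
  as_rearrangement(tab)
}

airr_required_cols <- c("sequence_id", "locus", "v_call", "j_call", "cdr3")
airr_optional_cols <- c(
  "cell_id", "c_call", "c_sequence", "tissue", "source",
  "duplicate_count", "v_identity", "v_sequence", "sequence"
)

#' Coerce and validate a rearrangement tibble
#'
#' Fills missing optional columns with their documented defaults, infers
#' `source` from `cell_id` presence, and checks the schema invariants
#' (unique `sequence_id`, CDR3 alphabet ACGTN, single-cell rows carry a
#' `cell_id`).
#'
#' @param tab a data frame with at least the required rearrangement columns.
#' @return A validated tibble in fixed column order.
#' @export
as_rearrangement <- function(tab) {
  tab <- as_tibble(tab)
  missing_cols <- setdiff(airr_required_cols, names(tab))
  if (length(missing_cols)) {
    abort(paste0(
      "rearrangement table lacks required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in airr_optional_cols) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  }
  tab$duplicate_count[is.na(tab$duplicate_count)] <- "1"
  tab$duplicate_count <- as.integer(tab$duplicate_count)
  tab$v_identity <- as.numeric(tab$v_identity)

  # source inferred from cell_id presence when absent
  infer <- ifelse(!is.na(tab$cell_id) & tab$cell_id != "", "single_cell", "bulk")
  tab$source <- ifelse(is.na(tab$source), infer, tab$source)

  if (anyDuplicated(tab$sequence_id)) {
    dup <- unique(tab$sequence_id[duplicated(tab$sequence_id)])
    abort(paste0("duplicate sequence_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  bad_locus <- setdiff(unique(tab$locus), c("IGH", "IGK", "IGL"))
  if (length(bad_locus)) {
    abort(paste0("invalid locus value(s): ", paste(bad_locus, collapse = ", ")))
  }
  bad_cdr3 <- is.na(tab$cdr3) | !grepl("^[ACGTN]+$", tab$cdr3)
  if (any(bad_cdr3)) {
    abort(paste0(
      "cdr3 must be a non-empty ACGTN string; offending sequence_id: ",
      paste(head(tab$sequence_id[bad_cdr3], 5), collapse = ", ")
    ))
  }
  sc_no_cell <- tab$source == "single_cell" & (is.na(tab$cell_id) | tab$cell_id == "")
  if (any(sc_no_cell)) {
    abort(paste0(
      "single_cell rows must carry cell_id; offending sequence_id: ",
      paste(head(tab$sequence_id[sc_no_cell], 5), collapse = ", ")
    ))
  }
  bad_vid <- !is.na(tab$v_identity) & (tab$v_identity < 0 | tab$v_identity > 1)
  if (any(bad_vid)) abort("v_identity must lie in [0, 1]")
  if (any(tab$duplicate_count < 1L)) abort("duplicate_count must be >= 1")

  extra <- setdiff(names(tab), c(airr_required_cols, airr_optional_cols))
  tab[, c(airr_required_cols, airr_optional_cols, extra)]
}

#' @rdname read_airr
#' @param tab a rearrangement tibble (validated via [as_rearrangement()]).
#' @export
write_airr <- function(tab, path) {
  tab <- as_rearrangement(tab)
  out <- tab
  out[] <- lapply(out, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
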