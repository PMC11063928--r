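#' Add the somatic-hypermutation percentage column
#'
#' `v_shm_percent = 100 * (1 - v_identity)` where `v_identity` is present;
#' otherwise computed from `v_sequence` against the germline V allele in
#' `v_refs` via [shm_percent()].
#'
#' @param records rearrangement tibble.
#' @param v_refs optional named vector of germline V sequences keyed by
#'   allele name.
#' @return The tibble with a `v_shm_percent` column.
#' @export
add_shm_percent <- function(records, v_refs = NULL) {
  shm <- ifelse(!is.na(records$v_identity),
                100 * (1 - records$v_identity), NA_real_)
  if (!is.null(v_refs)) {
    todo <- which(is.na(shm) & !is.na(records$v_sequence) &
                    records$v_call %in% names(v_refs))
    for (i in todo) {
      shm[i] <- shm_percent(records$v_sequence[i], v_refs[[records$v_call[i]]])
    }
  }
  records$v_shm_percent <- shm
  records
}

#' Trace lineages across bulk tissue libraries
#'
#' For every (lineage, tissue) pair with bulk members: the member count,
#' the duplicate-weighted read count, and the relative abundance. By
#' default relative abundance is the lineage's reads over the tissue
#' library's total reads (all bulk reads sequenced from that tissue, so
#' per-tissue abundances may sum to less than 1 when some reads belong to
#' no traced lineage); with `denominator = "traced"` the total is
#' restricted to reads of the traced lineages themselves.
#'
#' @param assigned lineage-annotated heavy-chain tibble from
#'   [infer_lineages()].
#' @param denominator `"library"` (default) or `"traced"`.
#' @param lineage_ids optional subset of lineages to trace (e.g. lineages
#'   seen in caecal single cells); default all.
#' @return Long tibble: `lineage_id`, `tissue`, `member_count`,
#'   `read_count`, `relative_abundance`. Sparse: absent combinations are
#'   omitted.
#' @export
trace_lineages <- function(assigned, denominator = c("library", "traced"),
                           lineage_ids = NULL) {
  denominator <- match.arg(denominator)
  bulk <- filter(assigned, source == "bulk", !is.na(tissue))
  totals <- bulk %>%
    group_by(tissue) %>%
    summarise(total_reads = sum(duplicate_count), .groups = "drop")
  if (any(totals$total_reads == 0)) {
    abort(paste0("tissue library with zero total reads: ",
                 paste(totals$tissue[totals$total_reads == 0], collapse = ", ")))
  }
  if (!is.null(lineage_ids)) bulk <- filter(bulk, lineage_id %in% lineage_ids)
  tab <- bulk %>%
    group_by(lineage_id, tissue) %>%
    summarise(member_count = n(), read_count = sum(duplicate_count),
              .groups = "drop")
  if (denominator == "traced") {
    totals <- tab %>%
      group_by(tissue) %>%
      summarise(total_reads = sum(read_count), .groups = "drop")
  }
  tab %>%
    left_join(totals, by = "tissue") %>%
    mutate(relative_abundance = read_count / .data$total_reads) %>%
    select(lineage_id, tissue, member_count, read_count, relative_abundance) %>%
    arrange(lineage_id, tissue)
}

#' SHM summary per compartment
#'
#' Distribution of heavy-chain V-gene somatic hypermutation for traced
#' lineage members, by tissue compartment: n, mean, median and quartiles
#' of `v_shm_percent`.
#'
#' @param assigned lineage-annotated heavy tibble with a `v_shm_percent`
#'   column (see [add_shm_percent()]).
#' @param compartments optional compartment set to report; compartments
#'   with no traced members get `n = 0` and `NA` statistics.
#' @return Tibble: `tissue`, `n`, `mean_shm`, `median_shm`, `q25`, `q75`.
#' @export
shm_by_compartment <- function(assigned, compartments = NULL) {
  if (!"v_shm_percent" %in% names(assigned)) {
    abort("v_shm_percent missing; call add_shm_percent() first")
  }
  with_shm <- filter(assigned, !is.na(v_shm_percent), !is.na(tissue))
  tab <- with_shm %>%
    group_by(tissue) %>%
    summarise(
      n = n(),
      mean_shm = mean(v_shm_percent),
      median_shm = median(v_shm_percent),
      q25 = unname(quantile(v_shm_percent, 0.25)),
      q75 = unname(quantile(v_shm_percent, 0.75)),
      .groups = "drop"
    )
  if (!is.null(compartments)) {
    missing_comp <- setdiff(compartments, tab$tissue)
    if (length(missing_comp)) {
      tab <- bind_rows(tab, tibble(
        tissue = missing_comp, n = 0L, mean_shm = NA_real_,
        median_shm = NA_real_, q25 = NA_real_, q75 = NA_real_
      ))
    }
    tab <- filter(tab, tissue %in% compartments)
  }
  arrange(tab, tissue)
}

#' Heavy-chain V and J usage
#'
#' Sequence counts per V gene and per J gene. Allele calls are collapsed
#' to the gene by stripping the `*NN` allele suffix (ambiguous comma-joined
#' calls use the first listed allele); set `by_allele = TRUE` to keep the
#' full allele granularity. Frequencies sum to 1 within each segment class.
#'
#' @param records heavy-chain rearrangement tibble.
#' @param by_allele report alleles instead of genes (default FALSE).
#' @return Tibble: `segment` ("V"/"J"), `gene`, `chain` ("heavy"),
#'   `count`, `frequency`.
#' @export
vj_usage <- function(records, by_allele = FALSE) {
  heavy <- filter(records, locus == "IGH")
  first_call <- function(x) sub(",.*$", "", x)
  collapse <- function(x) if (by_allele) first_call(x) else sub("\\*.*$", "", first_call(x))
  usage_of <- function(calls, segment) {
    tibble(gene = collapse(calls)) %>%
      count(gene, name = "count") %>%
      mutate(segment = segment, chain = "heavy",
             frequency = count / sum(count))
  }
  bind_rows(
    usage_of(heavy$v_call, "V"),
    usage_of(heavy$j_call, "J")
  ) %>%
    select(segment, gene, chain, count, frequency) %>%
    arrange(segment, dplyr::desc(count), gene)
}

#' Isotype composition of paired antibodies
#'
#' Count and percentage per isotype over paired single cells (percentages
#' sum to 100).
#'
#' @param tab tibble with one row per paired cell and an `isotype`
#'   column; `NA` isotypes are reported as `"unknown"`.
#' @return Tibble: `isotype`, `count`, `percentage`.
#' @export
isotype_composition <- function(tab) {
  if (!nrow(tab)) abort("no paired cells to summarise")
  if (!"isotype" %in% names(tab)) abort("isotype column missing")
  tab %>%
    mutate(isotype = ifelse(is.na(isotype), "unknown", isotype)) %>%
    count(isotype, name = "count") %>%
    mutate(percentage = 100 * count / sum(count)) %>%
    arrange(dplyr::desc(count), isotype)
}
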