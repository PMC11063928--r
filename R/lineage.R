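#' Cluster heavy chains into clonal lineages
#'
#' Lineages are defined over heavy-chain rearrangements (single-cell and
#' bulk combined) by identical V and J allele assignment and identical CDR3
#' length, permitting at most `threshold` nucleotide mismatches (as a
#' fraction of CDR3 length, inclusive) between CDR3s. Within each
#' (V allele, J allele, CDR3 length) key the mismatch predicate is closed
#' transitively (single linkage), so every pair of members is connected by a
#' chain of pairwise mismatch fractions at or below the threshold.
#'
#' Ambiguous multi-allele calls (comma-joined, e.g.
#' `"IGHV4-1*01,IGHV4-1*02"`) are compared as sets: keys whose V sets and J
#' sets both overlap are treated as identical and merged transitively.
#'
#' Lineage ids are deterministic: key groups are ordered by key string and
#' then by their smallest member `sequence_id`, and labelled `L0001`,
#' `L0002`, ... so the result is invariant to input row order.
#'
#' @param records rearrangement tibble (see [read_airr()]); all rows must be
#'   locus IGH.
#' @param threshold maximum CDR3 mismatch fraction joining two members
#'   (default 0.20, inclusive).
#' @return The input tibble with a `lineage_id` column and a
#'   `cdr3_length` column, ordered by lineage.
#' @examples
#' tab <- tibble::tibble(
#'   sequence_id = c("a", "b", "c"), locus = "IGH",
#'   v_call = "IGHV1-1*01", j_call = "IGHJ4*01",
#'   cdr3 = c("AAAAACCCCC", "AAAAACCCCG", "GGGGGTTTTT")
#' )
#' cluster_heavy_lineages(tab)$lineage_id
#' @export
cluster_heavy_lineages <- function(records, threshold = 0.20) {
  records <- as_rearrangement(records)
  if (any(records$locus != "IGH")) {
    abort("cluster_heavy_lineages expects heavy-chain (IGH) records only")
  }
  records$cdr3_length <- nchar(records$cdr3)

  key_of <- merge_allele_keys(records$v_call, records$j_call, records$cdr3_length)
  groups <- split(seq_len(nrow(records)), key_of)

  assignments <- lapply(groups, function(idx) {
    seqs <- records$cdr3[idx]
    cl <- single_linkage_clusters(seqs, threshold)
    split(idx, cl)
  })
  # flatten to member lists, one per lineage
  members <- unlist(unname(lapply(assignments, unname)), recursive = FALSE)

  # deterministic id order: key string, then smallest member sequence_id
  key_str <- vapply(members, function(idx) key_of[idx[1]], character(1))
  min_sid <- vapply(members, function(idx) min(records$sequence_id[idx]), character(1))
  ord <- order(key_str, min_sid)
  members <- members[ord]

  ids <- sprintf("L%04d", seq_along(members))
  lineage_id <- character(nrow(records))
  for (i in seq_along(members)) lineage_id[members[[i]]] <- ids[i]
  records$lineage_id <- lineage_id
  arrange(records, lineage_id, sequence_id)
}

# Group records by (V allele set, J allele set, CDR3 length), merging keys
# whose allele sets overlap (any-overlap counts as identical). Returns a
# canonical key string per record.
merge_allele_keys <- function(v_call, j_call, cdr3_length) {
  key <- paste(v_call, j_call, cdr3_length, sep = "|")
  uk <- sort(unique(key))
  n <- length(uk)
  parts <- strsplit(uk, "|", fixed = TRUE)
  vs <- lapply(parts, function(p) strsplit(p[1], ",", fixed = TRUE)[[1]])
  js <- lapply(parts, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]])
  ln <- vapply(parts, function(p) p[3], character(1))

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  ambiguous <- grepl(",", uk, fixed = TRUE)
  if (any(ambiguous)) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (!(ambiguous[i] || ambiguous[j])) next
        if (ln[i] != ln[j]) next
        if (length(intersect(vs[[i]], vs[[j]])) && length(intersect(js[[i]], js[[j]]))) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  canon <- uk[roots]
  names(canon) <- uk
  unname(canon[key])
}

# Single-linkage clustering of equal-length sequences under the mismatch
# fraction predicate; returns integer cluster labels.
single_linkage_clusters <- function(seqs, threshold) {
  n <- length(seqs)
  if (n == 1) return(1L)
  d <- hamming_matrix(seqs)
  tree <- hclust(as.dist(d), method = "single")
  # tiny epsilon keeps exact-threshold merges inclusive under floating point
  cutree(tree, h = threshold + 1e-12)
}

# Pairwise Hamming-fraction matrix for equal-length sequences.
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(seqs, ""))
  L <- ncol(chars)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    di <- rowSums(chars[seq(i + 1, n), , drop = FALSE] !=
                    matrix(chars[i, ], n - i, L, byrow = TRUE)) / L
    d[i, seq(i + 1, n)] <- di
    d[seq(i + 1, n), i] <- di
  }
  d
}

#' Pair heavy and light chains per cell
#'
#' Builds the paired-cell table from single-cell rearrangements: cells with
#' exactly one heavy (IGH) and one light (IGK or IGL) chain. Multi-chain
#' cells should already have been excluded by QC; any remaining ones are
#' dropped here with a warning.
#'
#' @param records rearrangement tibble containing single-cell rows.
#' @return Tibble with one row per paired cell: `cell_id`,
#'   `heavy_sequence_id`, `light_sequence_id`, `light_key` (light V allele /
#'   J allele / CDR3 length), and the light-chain columns.
#' @export
pair_cells <- function(records) {
  sc <- filter(as_rearrangement(records), source == "single_cell")
  heavy <- filter(sc, locus == "IGH")
  light <- filter(sc, locus %in% c("IGK", "IGL"))
  nh <- table(heavy$cell_id)
  nl <- table(light$cell_id)
  ok <- intersect(names(nh)[nh == 1], names(nl)[nl == 1])
  dropped <- setdiff(unique(sc$cell_id), ok)
  if (length(dropped)) {
    warn(sprintf("%d cell(s) without exactly one heavy and one light chain dropped in pairing",
                 length(dropped)))
  }
  heavy <- filter(heavy, cell_id %in% ok)
  light <- filter(light, cell_id %in% ok)
  light <- mutate(light,
    light_key = paste(v_call, j_call, nchar(cdr3), sep = "|")
  )
  out <- left_join(
    select(heavy, cell_id, heavy_sequence_id = sequence_id),
    select(light, cell_id,
           light_sequence_id = sequence_id, light_v_call = v_call,
           light_j_call = j_call, light_cdr3 = cdr3, light_key),
    by = "cell_id"
  )
  arrange(out, cell_id)
}

#' Refine lineages by light-chain assignment
#'
#' If single-cell members of a heavy-chain lineage carry different light
#' chains, the lineage is redefined by additionally requiring identical
#' light V and J allele assignment and identical light CDR3 length: the
#' single-cell members are split into one sub-lineage per light key
#' (`<id>.1`, `<id>.2`, ... ordered by light key string). Members carrying
#' no light chain (all bulk reads, plus any single-cell member without a
#' paired light chain) cannot be placed by this rule and are marked
#' `unassigned` for [resolve_divergent()]. Lineages whose members agree on
#' at most one light key are left unchanged.
#'
#' @param assigned output of [cluster_heavy_lineages()].
#' @param cells paired-cell table from [pair_cells()].
#' @return The input tibble with `lineage_id` rewritten for split lineages
#'   and a `stage` column: `heavy` (untouched), `light_split` (placed by
#'   light key) or `unassigned` (awaiting Levenshtein resolution).
#' @export
refine_by_light_chain <- function(assigned, cells) {
  assigned$stage <- "heavy"
  assigned$parent_lineage <- assigned$lineage_id
  key_by_cell <- setNames(cells$light_key, cells$cell_id)
  lid <- assigned$lineage_id
  for (id in unique(lid)) {
    idx <- which(lid == id)
    is_sc <- assigned$source[idx] == "single_cell"
    lkeys <- rep(NA_character_, length(idx))
    lkeys[is_sc] <- unname(key_by_cell[assigned$cell_id[idx][is_sc]])
    distinct_keys <- sort(unique(lkeys[!is.na(lkeys)]))
    if (length(distinct_keys) <= 1) next
    sub_ids <- setNames(
      sprintf("%s.%d", id, seq_along(distinct_keys)), distinct_keys
    )
    placed <- !is.na(lkeys)
    assigned$lineage_id[idx[placed]] <- unname(sub_ids[lkeys[placed]])
    assigned$stage[idx[placed]] <- "light_split"
    assigned$lineage_id[idx[!placed]] <- NA_character_
    assigned$stage[idx[!placed]] <- "unassigned"
  }
  assigned
}

#' Resolve members of light-chain-divergent lineages by Levenshtein distance
#'
#' Members left unplaced by [refine_by_light_chain()] (bulk heavy chains
#' and single-cell members without a paired light chain) are attached to the
#' sub-lineage whose single-cell heavy-chain CDR3s come closest by minimum
#' Levenshtein distance, using each single-cell heavy chain as reference.
#' Ties go to the lowest sub-lineage id (deterministic). If a parent
#' lineage has no sub-lineage with a single-cell reference, its unplaced
#' members stay together in a residual lineage flagged `unresolved`.
#'
#' @param refined output of [refine_by_light_chain()].
#' @return The tibble with every row assigned a `lineage_id`; resolved rows
#'   carry stage `levenshtein`, residual rows `unresolved`.
#' @export
resolve_divergent <- function(refined) {
  todo <- which(refined$stage == "unassigned")
  if (!length(todo)) return(refined)
  for (parent in unique(refined$parent_lineage[todo])) {
    rows <- todo[refined$parent_lineage[todo] == parent]
    subs <- refined[refined$parent_lineage == parent &
                      refined$stage == "light_split" &
                      refined$source == "single_cell", ]
    if (!nrow(subs)) {
      refined$lineage_id[rows] <- paste0(parent, ".U")
      refined$stage[rows] <- "unresolved"
      next
    }
    sub_ids <- sort(unique(subs$lineage_id))
    for (r in rows) {
      d <- adist(refined$cdr3[r], subs$cdr3)[1, ]
      best_per_sub <- vapply(sub_ids, function(s) min(d[subs$lineage_id == s]),
                             numeric(1))
      refined$lineage_id[r] <- sub_ids[which.min(best_per_sub)]
      refined$stage[r] <- "levenshtein"
    }
  }
  refined
}

#' Full lineage inference: clustering, light refinement, resolution
#'
#' Chains [cluster_heavy_lineages()], [refine_by_light_chain()] and
#' [resolve_divergent()] over combined single-cell and bulk heavy chains.
#'
#' @param records rearrangement tibble (heavy and light chains; light rows
#'   are used only for pairing).
#' @param threshold CDR3 mismatch fraction (default 0.20).
#' @return Heavy-chain tibble with final `lineage_id` and `stage` columns.
#' @examples
#' sim <- simulate_repertoire(repertoire_config(n_lineages = 5,
#'                                              n_sequences = 60, seed = 1))
#' lin <- infer_lineages(sim$records)
#' dplyr::n_distinct(lin$lineage_id)
#' @export
infer_lineages <- function(records, threshold = 0.20) {
  records <- as_rearrangement(records)
  heavy <- filter(records, locus == "IGH")
  cells <- pair_cells(records)
  heavy %>%
    cluster_heavy_lineages(threshold = threshold) %>%
    refine_by_light_chain(cells) %>%
    resolve_divergent()
}

#' Summarise lineages
#'
#' One row per lineage: key, member counts by source, tissues seen.
#'
#' @param assigned lineage-annotated tibble from [infer_lineages()].
#' @return Summary tibble ordered by descending member count.
#' @export
summarise_lineages <- function(assigned) {
  assigned %>%
    group_by(lineage_id) %>%
    summarise(
      v_call = v_call[1],
      j_call = j_call[1],
      cdr3_length = nchar(cdr3[1]),
      n_members = n(),
      n_single_cell = sum(source == "single_cell"),
      n_bulk = sum(source == "bulk"),
      tissues = paste(sort(unique(tissue[!is.na(tissue)])), collapse = ","),
      .groups = "drop"
    ) %>%
    arrange(dplyr::desc(n_members), lineage_id)
}
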