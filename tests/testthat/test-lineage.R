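heavy_tab <- function(cdr3, v = "IGHV1-1*01", j = "IGHJ4*01",
                      cell_id = NA_character_, tissue = NA_character_) {
  tibble::tibble(
    sequence_id = sprintf("s%02d", seq_along(cdr3)), locus = "IGH",
    v_call = v, j_call = j, cdr3 = cdr3, cell_id = cell_id, tissue = tissue
  )
}

test_that("hamming fraction matches hand values and the positional oracle", {
  expect_equal(hamming_fraction("ACGT", "ACGT"), 0)
  a <- "AAAAAAAAAAAAAAA"
  b <- "CAAAACAAAACAAAA" # 15-mers differing at 3 positions
  expect_equal(hamming_fraction(a, b), 0.2)
  expect_error(hamming_fraction("AC", "ACG"), "equal lengths")
  set.seed(5)
  for (i in 1:25) {
    x <- paste(sample(c("A", "C", "G", "T", "N"), 20, TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T", "N"), 20, TRUE), collapse = "")
    expect_equal(hamming_fraction(x, y), oracle_mismatch_fraction(x, y))
  }
})

test_that("Levenshtein distance matches the recursive oracle", {
  expect_equal(levenshtein_distance("", "ACG"), 3)
  expect_equal(levenshtein_distance("ACGTACG", "ACGTACG"), 0)
  set.seed(6)
  for (i in 1:60) {
    la <- sample(0:7, 1)
    lb <- sample(0:7, 1)
    a <- paste(sample(c("A", "C", "G", "T"), la, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), lb, TRUE), collapse = "")
    expect_equal(levenshtein_distance(a, b), oracle_levenshtein(a, b))
  }
})

test_that("lineage keys require identical V/J alleles and CDR3 length", {
  # identical CDR3s, same key: one lineage
  one <- cluster_heavy_lineages(heavy_tab(c("AAAAACCCCC", "AAAAACCCCC")))
  expect_equal(dplyr::n_distinct(one$lineage_id), 1)
  # different CDR3 lengths always separate
  two <- cluster_heavy_lineages(heavy_tab(c("AAAAACCCCC", "AAAAACCCCCG")))
  expect_equal(dplyr::n_distinct(two$lineage_id), 2)
  # different V alleles separate even with identical CDR3s
  tab <- heavy_tab(c("AAAAACCCCC", "AAAAACCCCC"))
  tab$v_call <- c("IGHV1-1*01", "IGHV2-1*01")
  tab$sequence_id <- c("x1", "x2")
  expect_equal(dplyr::n_distinct(cluster_heavy_lineages(tab)$lineage_id), 2)
  # non-IGH input is rejected
  bad <- heavy_tab("AAAA")
  bad$locus <- "IGK"
  expect_error(cluster_heavy_lineages(bad), "IGH")
})

test_that("single linkage chains members through the 20% threshold", {
  # 10-mers: a-b differ at 2 (0.2 <= 0.2 joins), b-c differ at 2, a-c at 4 (0.4)
  tab <- heavy_tab(c("AAAAAAAAAA", "CCAAAAAAAA", "CCCCAAAAAA"))
  res <- cluster_heavy_lineages(tab, threshold = 0.20)
  expect_equal(dplyr::n_distinct(res$lineage_id), 1)
  # at threshold 0.15 nothing joins
  res2 <- cluster_heavy_lineages(tab, threshold = 0.15)
  expect_equal(dplyr::n_distinct(res2$lineage_id), 3)
})

test_that("clustering equals the transitive-closure oracle and ignores row order", {
  set.seed(8)
  for (rep in 1:5) {
    tab <- random_heavy_records(60)
    res <- cluster_heavy_lineages(tab)
    oracle <- oracle_lineage_partition(tab)
    joined <- dplyr::inner_join(res, tibble::tibble(
      sequence_id = tab$sequence_id, oracle = oracle
    ), by = "sequence_id")
    expect_equal(mclust::adjustedRandIndex(joined$lineage_id, joined$oracle), 1)
    # row-order invariance, including the id labels
    shuffled <- tab[sample(nrow(tab)), ]
    res2 <- cluster_heavy_lineages(shuffled)
    expect_identical(res$lineage_id[order(res$sequence_id)],
                     res2$lineage_id[order(res2$sequence_id)])
  }
})

test_that("ambiguous multi-allele calls merge keys by set overlap", {
  tab <- heavy_tab(c("AAAAACCCCC", "AAAAACCCCC", "AAAAACCCCC"))
  tab$v_call <- c("IGHV1-1*01", "IGHV1-1*01,IGHV1-2*01", "IGHV1-2*01")
  res <- cluster_heavy_lineages(tab)
  expect_equal(dplyr::n_distinct(res$lineage_id), 1)
})

test_that("light-chain refinement splits lineages with divergent light keys", {
  tab <- heavy_tab(c("AAAAACCCCC", "AAAAACCCCG", "AAAAACCCTT", "AAAAACCCCA"),
                   cell_id = c("c1", "c2", NA, NA))
  tab$tissue <- c("caecum", "caecum", "spleen", "spleen")
  light <- tibble::tibble(
    sequence_id = c("l1", "l2"), locus = c("IGK", "IGL"),
    v_call = c("IGKV1-1*01", "IGLV2-1*01"),
    j_call = c("IGKJ2*01", "IGLJ3*01"),
    cdr3 = c("AAACCCGGG", "AAACCCGGGTT"),
    cell_id = c("c1", "c2")
  )
  records <- dplyr::bind_rows(tab, light)
  cells <- pair_cells(records)
  clustered <- cluster_heavy_lineages(as_rearrangement(tab))
  expect_equal(dplyr::n_distinct(clustered$lineage_id), 1)
  refined <- refine_by_light_chain(clustered, cells)
  # two sub-lineages, bulk members unassigned for Levenshtein resolution
  split_ids <- refined$lineage_id[refined$stage == "light_split"]
  expect_equal(dplyr::n_distinct(split_ids), 2)
  expect_equal(sum(refined$stage == "unassigned"), 2)
  # no member lost or duplicated
  expect_setequal(refined$sequence_id, tab$sequence_id)
  resolved <- resolve_divergent(refined)
  expect_false(any(is.na(resolved$lineage_id)))
  expect_setequal(resolved$sequence_id, tab$sequence_id)
  # s3 (AAAAACCCTT) is Levenshtein-closer to c2's heavy (AAAAACCCCG)?
  # distances: to s1 AAAAACCCCC = 2, to s2 AAAAACCCCG = 2 -> tie, lowest id
  s3 <- resolved[resolved$sequence_id == "s03", ]
  expect_equal(s3$stage, "levenshtein")
  expect_equal(s3$lineage_id, sort(unique(split_ids))[1])
})

test_that("lineages sharing one light key are left intact", {
  tab <- heavy_tab(c("AAAAACCCCC", "AAAAACCCCG"), cell_id = c("c1", "c2"))
  light <- tibble::tibble(
    sequence_id = c("l1", "l2"), locus = "IGK",
    v_call = "IGKV1-1*01", j_call = "IGKJ2*01",
    cdr3 = c("AAACCCGGG", "AAACCCGGT"), cell_id = c("c1", "c2")
  )
  records <- dplyr::bind_rows(tab, light)
  refined <- refine_by_light_chain(
    cluster_heavy_lineages(as_rearrangement(tab)),
    pair_cells(records)
  )
  expect_equal(dplyr::n_distinct(refined$lineage_id), 1)
  expect_true(all(refined$stage == "heavy"))
})

test_that("bulk members join the sub-lineage at minimum Levenshtein distance", {
  # one heavy lineage chained through the threshold, two light keys
  tab <- heavy_tab(
    c("AAAAAAAAAA", "AAAACCAAAA", "AAAAAAAAAG", "AAAACCAAAG"),
    cell_id = c("c1", "c2", NA, NA)
  )
  light <- tibble::tibble(
    sequence_id = c("l1", "l2"), locus = c("IGK", "IGL"),
    v_call = c("IGKV1-1*01", "IGLV2-1*01"),
    j_call = c("IGKJ2*01", "IGLJ3*01"),
    cdr3 = c("AAACCCGGG", "AAACCCGGGTT"), cell_id = c("c1", "c2")
  )
  res <- infer_lineages(dplyr::bind_rows(tab, light))
  # s3 is 1 edit from c1's heavy, 7 from c2's: joins c1's sub-lineage
  expect_equal(res$lineage_id[res$sequence_id == "s03"],
               res$lineage_id[res$sequence_id == "s01"])
  expect_equal(res$lineage_id[res$sequence_id == "s04"],
               res$lineage_id[res$sequence_id == "s02"])
})

test_that("isotype assignment recovers exact and mutated constant regions", {
  set.seed(10)
  refs <- c(
    IgA = paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
    IgG1 = paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
    IgM = paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  )
  expect_equal(assign_isotype(substr(refs[["IgA"]], 1, 60), refs), "IgA")
  expect_equal(assign_isotype(NA_character_, refs), "unknown")
  expect_equal(assign_isotype("", refs), "unknown")
  # 2 substitutions in 100 nt: identity 0.98 >= 0.9
  mutated <- refs[["IgG1"]]
  substr(mutated, 5, 5) <- ifelse(substr(mutated, 5, 5) == "A", "C", "A")
  substr(mutated, 50, 50) <- ifelse(substr(mutated, 50, 50) == "G", "T", "G")
  expect_equal(assign_isotype(mutated, refs, min_score = 0.9), "IgG1")
  # below min_score the call is unknown
  expect_equal(assign_isotype(paste(rep("A", 100), collapse = ""),
                              refs["IgM"], min_score = 0.9), "unknown")
  expect_error(assign_isotype("ACGT", c()), "empty")
})

test_that("SHM percentage counts mismatches and skips N positions", {
  a <- paste(rep("A", 200), collapse = "")
  expect_equal(shm_percent(a, a), 0)
  b <- a
  substr(b, 1, 2) <- "GG"
  expect_equal(shm_percent(b, a), 1.0) # 2 in 200
  # N positions excluded from numerator and denominator
  c1 <- "ANGT"
  c2 <- "AAGT"
  expect_equal(shm_percent(c1, c2), 0)
  expect_equal(shm_percent("NNNT", "NNNA"), 100)
  expect_error(shm_percent("NNNN", "NNNN"), "comparable")
  set.seed(12)
  for (i in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    expect_equal(shm_percent(x, y), 100 * oracle_mismatch_fraction(x, y))
  }
})

test_that("clean synthetic repertoires are recovered perfectly (ARI 1)", {
  sim <- simulate_repertoire(repertoire_config(
    n_lineages = 20, n_sequences = 300, seed = 14
  ))
  res <- infer_lineages(sim$records)
  expect_equal(lineage_recovery_ari(res, sim$truth$sequences), 1)
  # partition property: every heavy record in exactly one lineage
  heavy_ids <- sim$records$sequence_id[sim$records$locus == "IGH"]
  expect_setequal(res$sequence_id, heavy_ids)
  expect_false(any(is.na(res$lineage_id)))
})
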