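# Independent oracles used to cross-check the implementation. These are
# deliberately naive (brute force, recursion, closed forms) and share no
# code with the package internals.

# Transitive closure of the pairwise lineage predicate: same exact
# (v_call, j_call, CDR3 length) key and hamming fraction <= threshold,
# closed by repeated sweeps until no labels change. O(n^2) per sweep.
oracle_lineage_partition <- function(records, threshold = 0.20) {
  n <- nrow(records)
  key <- paste(records$v_call, records$j_call, nchar(records$cdr3), sep = "/")
  lab <- seq_len(n)
  ham <- function(a, b) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    mean(av != bv)
  }
  linked <- function(i, j) {
    key[i] == key[j] && ham(records$cdr3[i], records$cdr3[j]) <= threshold
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (lab[i] != lab[j] && linked(i, j)) {
          new <- min(lab[i], lab[j])
          lab[lab == lab[i] | lab == lab[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# Exponential-time recursive Levenshtein (memoisation deliberately absent);
# character vectors indexed in place so the recursion itself is the only
# cost. Only for strings of length <= 7.
oracle_levenshtein <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(av)) return(length(bv) - j + 1L)
    if (j > length(bv)) return(length(av) - i + 1L)
    cost <- as.integer(av[i] != bv[j])
    min(rec(i + 1L, j) + 1L,
        rec(i, j + 1L) + 1L,
        rec(i + 1L, j + 1L) + cost)
  }
  rec(1L, 1L)
}

# Closed-form percent-deviance statistic via group means: for a Gaussian
# identity GLM on a binary indicator, 100 * (TSS - RSS) / TSS with RSS the
# two-group-mean residual sum of squares (= 100 * squared point-biserial
# correlation).
oracle_percent_deviance <- function(y, indicator) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  g0 <- y[indicator == 0]
  g1 <- y[indicator == 1]
  rss <- sum((g0 - mean(g0))^2) + sum((g1 - mean(g1))^2)
  100 * (tss - rss) / tss
}

# Positional mismatch fraction by explicit loop.
oracle_mismatch_fraction <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  d <- 0L
  for (i in seq_along(av)) if (av[i] != bv[i]) d <- d + 1L
  d / length(av)
}

# Random rearrangement table over few keys and two CDR3 lengths, built to
# produce borderline chains for the clustering oracle comparisons.
random_heavy_records <- function(n, n_keys = 4, lengths = c(12L, 15L)) {
  base_cdr3 <- lapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  })
  keys <- tibble::tibble(
    v_call = sprintf("IGHV%d-1*01", sample(1:3, n_keys, replace = TRUE)),
    j_call = sprintf("IGHJ%d*01", sample(1:2, n_keys, replace = TRUE)),
    len_i = sample(seq_along(lengths), n_keys, replace = TRUE)
  )
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(n_keys, 1)
    L <- lengths[keys$len_i[k]]
    cdr3 <- strsplit(base_cdr3[[keys$len_i[k]]], "")[[1]]
    nmut <- sample(0:ceiling(0.5 * L), 1)
    pos <- sample(L, nmut)
    cdr3[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    tibble::tibble(
      sequence_id = sprintf("R%04d", i), locus = "IGH",
      v_call = keys$v_call[k], j_call = keys$j_call[k],
      cdr3 = paste(cdr3, collapse = "")
    )
  })
  dplyr::bind_rows(rows)
}

# Jaccard index between two gene sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
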