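#' Quality-control filtering of cells
#'
#' Removes cells in the documented order:
#' \enumerate{
#'   \item mitochondrial fraction strictly greater than
#'     `mito_max_fraction` (more than 10% of reads mapping to
#'     mitochondrial genes);
#'   \item total UMIs strictly below `min_umi` or detected genes strictly
#'     below `min_genes` ("fewer than" is strict, so a cell at exactly
#'     1200 UMIs and 500 genes is retained);
#'   \item cells flagged as doublets upstream (`doublet_flag`);
#'   \item cells expressing more than one IG heavy or more than one IG
#'     light chain.
#' }
#' The four rules are independent predicates, so the ordered application
#' equals their conjunction; the order only attributes each removal to the
#' first rule that catches it in the report.
#'
#' @param m an `expr_matrix` (see [expression_matrix()]).
#' @param cfg a [default_config()] holding the thresholds.
#' @return A list with `matrix` (the filtered `expr_matrix`) and `report`
#'   (tibble: rule, n_removed, plus a final row with survivors).
#' @examples
#' sim <- simulate_expression(expression_config(n_cells = 60, seed = 1))
#' qc <- qc_filter_cells(sim$matrix, default_config())
#' qc$report
#' @export
qc_filter_cells <- function(m, cfg = default_config()) {
  cells <- m$cells
  needed <- c("mito_fraction", "total_umi", "n_genes_detected",
              "doublet_flag", "n_heavy_chains", "n_light_chains")
  for (col in needed) {
    if (!col %in% names(cells)) {
      abort(paste0("cell metadata lacks required column: ", col))
    }
  }
  alive <- rep(TRUE, nrow(cells))
  removed <- integer(4)

  r1 <- alive & cells$mito_fraction > cfg$mito_max_fraction
  removed[1] <- sum(r1)
  alive <- alive & !r1

  r2 <- alive & (cells$total_umi < cfg$min_umi |
                   cells$n_genes_detected < cfg$min_genes)
  removed[2] <- sum(r2)
  alive <- alive & !r2

  r3 <- alive & !is.na(cells$doublet_flag) & cells$doublet_flag
  removed[3] <- sum(r3)
  alive <- alive & !r3

  r4 <- alive & ((!is.na(cells$n_heavy_chains) & cells$n_heavy_chains > 1) |
                   (!is.na(cells$n_light_chains) & cells$n_light_chains > 1))
  removed[4] <- sum(r4)
  alive <- alive & !r4

  report <- tibble(
    rule = c("high_mito_fraction", "low_umi_or_genes", "doublet",
             "multi_ig_chain", "retained"),
    n_removed = c(removed, NA_integer_),
    n_cells = c(rep(NA_integer_, 4), sum(alive))
  )
  out <- m
  out$counts <- m$counts[, alive, drop = FALSE]
  out$cells <- cells[alive, , drop = FALSE]
  list(matrix = out, report = report)
}

#' Remove low-prevalence genes
#'
#' Genes detected (nonzero count) in fewer than `min_cells_per_gene` cells
#' are excluded; "fewer than" is strict, so a gene seen in exactly 10 cells
#' is kept at the default threshold.
#'
#' @param m an `expr_matrix`, cells already QC-filtered.
#' @param cfg a [default_config()].
#' @return The `expr_matrix` restricted to retained genes.
#' @export
filter_genes <- function(m, cfg = default_config()) {
  n_cells_expressing <- Matrix::rowSums(m$counts > 0)
  keep <- n_cells_expressing >= cfg$min_cells_per_gene
  out <- m
  out$counts <- m$counts[keep, , drop = FALSE]
  out$genes <- m$genes[keep, , drop = FALSE]
  out
}

#' Library-size normalization and log transform
#'
#' Scales each cell's counts to the median library size across cells, then
#' applies `log(1 + x)`. Deterministic; cells with proportional raw
#' profiles map to identical normalized profiles.
#'
#' @param m an `expr_matrix` after QC (no zero-total cells).
#' @return A dense genes-by-cells matrix of normalized log expression.
#' @export
normalize_log <- function(m) {
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0)) {
    abort("zero-total cell(s) present; run qc_filter_cells first")
  }
  target <- median(totals)
  x <- as.matrix(m$counts) %*% diag(target / totals, length(totals))
  colnames(x) <- colnames(m$counts)
  log1p(x)
}

#' Select highly variable genes by standardized dispersion
#'
#' Ranks genes by the dispersion of their variance-stabilized expression:
#' per-gene variance of the log-normalized matrix is standardized (z-score)
#' within 20 equal-frequency bins of mean expression, and the top `n`
#' genes are returned. Ties are broken lexicographically by gene name so
#' the selection is deterministic.
#'
#' @param x normalized matrix from [normalize_log()].
#' @param n number of genes to select (default 3000).
#' @return Character vector of `n` gene names, ranked.
#' @export
select_hvg <- function(x, n = 3000L) {
  if (n > nrow(x)) {
    abort(sprintf("cannot select %d HVGs from %d genes", n, nrow(x)))
  }
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  bins <- cut(rank(mu, ties.method = "first"), breaks = 20, labels = FALSE)
  z <- v
  for (b in unique(bins)) {
    i <- bins == b
    s <- sd(v[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (v[i] - mean(v[i])) / s
  }
  ord <- order(-z, rownames(x))
  rownames(x)[ord][seq_len(n)]
}
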