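#' Mitochondrially encoded OXPHOS gene set
#'
#' The electron-transport-chain transcripts commonly used to compare
#' metabolic state between clusters (cytochrome c oxidase, NADH
#' dehydrogenase and ATP synthase subunits).
#'
#' @return Character vector of gene symbols.
#' @export
oxphos_mito_genes <- function() {
  c("COX1", "COX2", "COX3", "COX4I1", "COX5A", "COX5B",
    "ND1", "ND2", "ND3", "ND4", "ND5", "ATP6")
}

#' Per-cluster gene-set scores and fold changes
#'
#' For each gene set and cluster: the mean normalized expression of the
#' set's genes over the cluster's cells, and the log2 fold change of that
#' mean against all remaining cells,
#' `log2((mean_in + eps) / (mean_rest + eps))` with a documented
#' pseudocount `eps` guarding against division by zero.
#'
#' @param x normalized genes-by-cells matrix.
#' @param gene_sets named list of character vectors of gene names; each set
#'   must intersect the matrix genes.
#' @param cluster_labels per-cell cluster labels.
#' @param eps pseudocount (default 1e-9).
#' @return Tibble: `gene_set`, `cluster_id`, `n_genes_used`,
#'   `mean_expression`, `log2_fold_change`.
#' @export
gene_set_score <- function(x, gene_sets, cluster_labels, eps = 1e-9) {
  cluster_labels <- as.character(cluster_labels)
  if (length(cluster_labels) != ncol(x)) {
    abort("cluster_labels must match the number of cells")
  }
  if (is.null(names(gene_sets))) abort("gene_sets must be a named list")
  clusters <- sort(unique(cluster_labels))
  rows <- list()
  for (set_name in names(gene_sets)) {
    genes <- intersect(gene_sets[[set_name]], rownames(x))
    if (!length(genes)) {
      abort(paste0("gene set '", set_name, "' shares no genes with the matrix"))
    }
    sub <- x[genes, , drop = FALSE]
    for (cl in clusters) {
      in_cl <- cluster_labels == cl
      mean_in <- mean(sub[, in_cl, drop = FALSE])
      mean_rest <- mean(sub[, !in_cl, drop = FALSE])
      rows[[length(rows) + 1]] <- tibble(
        gene_set = set_name, cluster_id = cl,
        n_genes_used = length(genes),
        mean_expression = mean_in,
        log2_fold_change = log2((mean_in + eps) / (mean_rest + eps))
      )
    }
  }
  bind_rows(rows)
}
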