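#' Soft-threshold co-expression adjacency
#'
#' Unsigned weighted-network adjacency between genes:
#' `a_ij = |cor(gene_i, gene_j)|^power` with zero diagonal. Anti-correlated
#' genes are as adjacent as correlated ones (unsigned network). Genes with
#' zero variance have undefined correlations; these are set to 0 with a
#' warning.
#'
#' @param x normalized genes-by-cells matrix (HVG subset).
#' @param power soft-threshold exponent (default 6, the usual convention
#'   for unsigned networks).
#' @return Symmetric gene-by-gene matrix with entries in \[0,1\] and zero
#'   diagonal.
#' @export
build_adjacency <- function(x, power = 6) {
  if (nrow(x) < 2) abort("need at least 2 genes")
  v <- apply(x, 1, var)
  if (any(v == 0)) {
    warn(sprintf("%d zero-variance gene(s); their adjacencies set to 0", sum(v == 0)))
  }
  a <- abs(suppressWarnings(cor(t(x))))^power
  a[!is.finite(a)] <- 0
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' Similarity between genes combining direct adjacency and shared network
#' neighbourhood (unsigned TOM):
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu` and `TOM_ii = 1`.
#'
#' @param a adjacency from [build_adjacency()].
#' @return Symmetric matrix with entries in \[0,1\], unit diagonal.
#' @examples
#' a <- matrix(0.5, 3, 3); diag(a) <- 0
#' compute_tom(a)[1, 2] # (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
#' @export
compute_tom <- function(a) {
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Cut gene modules from the topological overlap tree
#'
#' Hierarchical clustering of genes on dissimilarity `1 - TOM` with Ward's
#' linkage, cut to exactly `k` modules. The modules partition the gene set.
#'
#' @param tom topological overlap matrix from [compute_tom()].
#' @param k number of modules (default 100).
#' @return Tibble (gene, module_id) with `module_id` in `1..k`.
#' @export
cut_modules <- function(tom, k = 100L) {
  if (k > nrow(tom)) {
    abort(sprintf("cannot cut %d modules from %d genes", k, nrow(tom)))
  }
  tree <- hclust(as.dist(1 - tom), method = "ward.D2")
  membership <- cutree(tree, k = k)
  tibble(gene = rownames(tom), module_id = as.integer(membership))
}

#' Per-cell module scores
#'
#' Each gene's cross-cell expression vector is rescaled to unit Euclidean
#' norm; because normalized log expression is non-negative this bounds
#' every value to \[0,1\]. A module's score in a cell is the mean of its
#' genes' rescaled values. All-zero genes contribute 0.
#'
#' @param x normalized genes-by-cells matrix (HVG subset).
#' @param modules tibble (gene, module_id) from [cut_modules()].
#' @return Modules-by-cells matrix of scores in \[0,1\], rownames
#'   `module_id`.
#' @export
score_modules <- function(x, modules) {
  if (!all(modules$gene %in% rownames(x))) {
    abort("modules reference genes absent from the matrix")
  }
  xs <- x[modules$gene, , drop = FALSE]
  norms <- sqrt(rowSums(xs^2))
  norms[norms == 0] <- 1 # all-zero gene scores 0 everywhere
  u <- xs / norms
  ids <- sort(unique(modules$module_id))
  scores <- t(vapply(ids, function(id) {
    colMeans(u[modules$gene[modules$module_id == id], , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(scores) <- ids
  colnames(scores) <- colnames(x)
  scores
}

#' Percent-deviance association between module scores and cell clusters
#'
#' For every (module, cluster) pair a Gaussian identity-link GLM of the
#' per-cell module score on the one-vs-rest indicator of that cluster is
#' fitted. For this family the residual deviance is the residual sum of
#' squares, so the statistic
#' `100 * (D_null - D_fit) / D_null`
#' is the percent reduction in deviance over the intercept-only null —
#' equivalently 100 times the squared point-biserial correlation — and
#' measures how strongly that cluster shifts the module's expression.
#' Constant scores have zero null deviance; their statistic is defined
#' as 0 (with a warning).
#'
#' @param scores modules-by-cells score matrix from [score_modules()].
#' @param cluster_labels per-cell cluster labels (length `ncol(scores)`).
#' @return An object of class `module_association`; use [tidy()] for the
#'   per-(module, cluster) table and [glance()] for a one-row summary.
#' @export
test_module_association <- function(scores, cluster_labels) {
  cluster_labels <- as.character(cluster_labels)
  if (length(cluster_labels) != ncol(scores)) {
    abort("cluster_labels must match the number of cells")
  }
  clusters <- sort(unique(cluster_labels))
  if (length(clusters) < 2) abort("need at least 2 clusters")

  rows <- list()
  warned_const <- FALSE
  for (mi in seq_len(nrow(scores))) {
    y <- scores[mi, ]
    for (cl in clusters) {
      ind <- as.integer(cluster_labels == cl)
      fit <- glm(y ~ ind, family = gaussian())
      d_null <- fit$null.deviance
      d_fit <- fit$deviance
      stat <- if (d_null > 0) 100 * (d_null - d_fit) / d_null else 0
      if (d_null == 0) warned_const <- TRUE
      rows[[length(rows) + 1]] <- tibble(
        module_id = rownames(scores)[mi], cluster_id = cl,
        percent_deviance_difference = stat,
        residual_deviance_fit = d_fit, residual_deviance_null = d_null
      )
    }
  }
  if (warned_const) warn("constant module score(s); their statistic is 0")
  structure(
    list(table = bind_rows(rows),
         n_modules = nrow(scores), n_clusters = length(clusters),
         n_cells = ncol(scores)),
    class = "module_association"
  )
}

#' @export
print.module_association <- function(x, ...) {
  cat("<module_association> ", x$n_modules, " modules x ", x$n_clusters,
      " clusters over ", x$n_cells, " cells\n", sep = "")
  print(head(arrange(x$table, dplyr::desc(percent_deviance_difference)), 5))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the module-cluster association table
#'
#' @param x a `module_association` from [test_module_association()].
#' @param ... unused.
#' @return Tibble with one row per (module, cluster): `module_id`,
#'   `cluster_id`, `percent_deviance_difference`,
#'   `residual_deviance_fit`, `residual_deviance_null`.
#' @method tidy module_association
#' @export
tidy.module_association <- function(x, ...) x$table

#' One-row summary of a module-association fit
#'
#' @param x a `module_association`.
#' @param ... unused.
#' @return Tibble: numbers of modules/clusters/cells and the maximum
#'   percent-deviance difference observed.
#' @method glance module_association
#' @export
glance.module_association <- function(x, ...) {
  tibble(
    n_modules = x$n_modules, n_clusters = x$n_clusters, n_cells = x$n_cells,
    max_percent_deviance = max(x$table$percent_deviance_difference)
  )
}
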