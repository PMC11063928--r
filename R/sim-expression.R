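#' Expression simulation configuration
#'
#' Parameters of the synthetic genes-by-cells count generator. Counts are
#' negative-binomial with log-mean
#' `baseline + cluster effect + loading * module latent factor`, giving a
#' matrix with cluster-structured correlated gene modules, mitochondrially
#' encoded genes, and a small set of planted quality-control failures, each
#' violating exactly one stated threshold. The defaults are desk-scale
#' (hundreds of cells and genes) but keep typical droplet depths: normal
#' cells carry roughly 2000 UMIs over ~600 detected genes with ~5%
#' mitochondrial reads, so the study thresholds (10% mito, 1200 UMIs, 500
#' genes) cleanly separate planted failures from normal cells.
#'
#' @param n_cells,n_genes matrix dimensions before planting failures
#'   (defaults 400 cells, 800 genes).
#' @param n_clusters number of cell clusters (default 3).
#' @param n_modules,module_size number and size of planted co-expression
#'   modules (defaults 4 modules of 10 genes).
#' @param within_module_correlation latent-factor loading in \[0,1\]
#'   shared by genes of a module (default 0.9).
#' @param cluster_effect log-fold effect of a cluster on its marker genes
#'   (default log(3)).
#' @param nb_dispersion negative-binomial size parameter (default 2).
#' @param mito_gene_count number of `MT-` genes (default 5).
#' @param planted_high_mito,planted_low_umi,planted_low_gene,planted_doublet,planted_multi_chain
#'   counts of planted failure cells per rule (defaults 2 each).
#' @param seed integer RNG seed.
#' @return A validated list of class `expression_config`.
#' @export
expression_config <- function(n_cells = 400L, n_genes = 800L,
                              n_clusters = 3L,
                              n_modules = 4L, module_size = 10L,
                              within_module_correlation = 0.9,
                              cluster_effect = log(3),
                              nb_dispersion = 2,
                              mito_gene_count = 5L,
                              planted_high_mito = 2L,
                              planted_low_umi = 2L,
                              planted_low_gene = 2L,
                              planted_doublet = 2L,
                              planted_multi_chain = 2L,
                              seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    n_clusters = as.integer(n_clusters),
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    within_module_correlation = within_module_correlation,
    cluster_effect = cluster_effect,
    nb_dispersion = nb_dispersion,
    mito_gene_count = as.integer(mito_gene_count),
    planted_high_mito = as.integer(planted_high_mito),
    planted_low_umi = as.integer(planted_low_umi),
    planted_low_gene = as.integer(planted_low_gene),
    planted_doublet = as.integer(planted_doublet),
    planted_multi_chain = as.integer(planted_multi_chain),
    seed = as.integer(seed)
  )
  if (cfg$n_modules * cfg$module_size > cfg$n_genes - cfg$mito_gene_count) {
    abort("n_modules * module_size must fit among non-mitochondrial genes")
  }
  if (cfg$within_module_correlation < 0 || cfg$within_module_correlation > 1) {
    abort("within_module_correlation must lie in [0, 1]")
  }
  if (cfg$nb_dispersion <= 0) abort("nb_dispersion must be positive")
  if (cfg$n_genes < 600L) {
    abort("n_genes must be >= 600 so normal cells can clear the 500-gene floor")
  }
  structure(cfg, class = c("expression_config", "list"))
}

#' Simulate a count matrix with planted modules, clusters and QC failures
#'
#' See [expression_config()] for the generative model. Planted failure
#' cells are constructed, not sampled: the high-mito cell's mitochondrial
#' counts are rescaled to a 15% fraction; the low-UMI cell carries ~700
#' UMIs over >600 genes; the low-gene cell carries 1200 UMIs over 400
#' genes; doublet and multi-chain cells are normal cells whose metadata
#' flags are set. Each therefore violates exactly one QC rule. The output
#' is a pure function of the configuration.
#'
#' @param config an [expression_config()].
#' @return A list with
#'   \describe{
#'     \item{matrix}{an `expr_matrix` (see [expression_matrix()]) whose cell
#'       metadata carries cluster labels, doublet flags and chain counts.}
#'     \item{truth}{ground truth: `modules` (gene, true_module),
#'       `cells` (cell_id, true_cluster, planted_failure).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_expression(expression_config(n_cells = 50, seed = 3))
#' dim(sim$matrix)
#' @export
simulate_expression <- function(config = expression_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    n_mito <- cfg$mito_gene_count
    gene_names <- c(
      sprintf("MT-SIM%d", seq_len(n_mito)),
      sprintf("GENE%04d", seq_len(cfg$n_genes - n_mito))
    )
    mito <- startsWith(gene_names, "MT-")

    # baseline log-means: mito genes deep (~5% of reads), others lognormal
    base <- numeric(cfg$n_genes)
    base[mito] <- log(20)
    base[!mito] <- rnorm(cfg$n_genes - n_mito, mean = log(2), sd = 0.6)

    # module membership among non-mito genes
    nonmito_idx <- which(!mito)
    module_of <- rep(NA_integer_, cfg$n_genes)
    if (cfg$n_modules > 0) {
      picked <- nonmito_idx[seq_len(cfg$n_modules * cfg$module_size)]
      module_of[picked] <- rep(seq_len(cfg$n_modules), each = cfg$module_size)
    }

    # cluster structure: labels + marker-gene effects
    cluster <- sample(sprintf("cl%d", seq_len(cfg$n_clusters)),
                      cfg$n_cells, replace = TRUE)
    marker_sets <- lapply(seq_len(cfg$n_clusters), function(k) {
      sample(nonmito_idx[is.na(module_of[nonmito_idx])],
             max(5L, round(0.05 * cfg$n_genes)))
    })
    # modules are driven by cluster-shifted latent factors so module scores
    # associate with clusters downstream
    module_cluster_shift <- matrix(
      rnorm(cfg$n_modules * cfg$n_clusters, 0, 1),
      cfg$n_modules, cfg$n_clusters
    )

    # mitochondrial transcripts are deep and weakly overdispersed; keeping
    # their dispersion low stops normal cells breaching the mito threshold
    size_vec <- ifelse(mito, 20, cfg$nb_dispersion)

    counts <- matrix(0L, cfg$n_genes, cfg$n_cells)
    cl_int <- as.integer(factor(cluster, levels = sprintf("cl%d", seq_len(cfg$n_clusters))))
    for (cell in seq_len(cfg$n_cells)) {
      lmu <- base
      k <- cl_int[cell]
      lmu[marker_sets[[k]]] <- lmu[marker_sets[[k]]] + cfg$cluster_effect
      if (cfg$n_modules > 0) {
        f <- module_cluster_shift[, k] + rnorm(cfg$n_modules, 0, 0.5)
        in_mod <- !is.na(module_of)
        lmu[in_mod] <- lmu[in_mod] +
          cfg$within_module_correlation * f[module_of[in_mod]]
      }
      counts[, cell] <- rnbinom(cfg$n_genes, mu = exp(lmu), size = size_vec)
    }
    cell_ids <- sprintf("CELL%04d", seq_len(cfg$n_cells))

    # planted failure cells, constructed to violate exactly one rule each
    planted <- list()
    add_planted <- function(kind, n, builder) {
      for (i in seq_len(n)) {
        planted[[length(planted) + 1]] <<- list(kind = kind, col = builder())
      }
    }
    normal_col <- function() {
      k <- sample(cfg$n_clusters, 1)
      lmu <- base
      lmu[marker_sets[[k]]] <- lmu[marker_sets[[k]]] + cfg$cluster_effect
      rnbinom(cfg$n_genes, mu = exp(lmu), size = size_vec)
    }
    add_planted("high_mito", cfg$planted_high_mito, function() {
      x <- normal_col()
      nm_total <- sum(x[!mito])
      target_m <- ceiling(0.15 * nm_total / 0.85) # mito fraction ~0.15 > 0.10
      x[mito] <- diff(round(seq(0, target_m, length.out = n_mito + 1)))
      x
    })
    add_planted("low_umi", cfg$planted_low_umi, function() {
      x <- integer(cfg$n_genes)
      x[seq_len(min(650L, cfg$n_genes))] <- 1L # ~650 UMIs, 650 genes
      x
    })
    add_planted("low_gene", cfg$planted_low_gene, function() {
      x <- integer(cfg$n_genes)
      x[sample(cfg$n_genes, 400L)] <- 3L # 1200 UMIs over 400 genes
      x
    })
    add_planted("doublet", cfg$planted_doublet, normal_col)
    add_planted("multi_chain", cfg$planted_multi_chain, normal_col)

    if (length(planted)) {
      extra <- vapply(planted, function(p) as.integer(p$col),
                      integer(cfg$n_genes))
      counts <- cbind(counts, extra)
      kinds <- vapply(planted, function(p) p$kind, character(1))
      cell_ids <- c(cell_ids,
                    sprintf("PLANT_%s_%d", kinds, seq_along(kinds)))
      cluster <- c(cluster,
                   sample(sprintf("cl%d", seq_len(cfg$n_clusters)),
                          length(planted), replace = TRUE))
      planted_kind <- c(rep(NA_character_, cfg$n_cells), kinds)
    } else {
      planted_kind <- rep(NA_character_, cfg$n_cells)
    }
    dimnames(counts) <- list(gene_names, cell_ids)

    meta <- tibble(
      cell_id = cell_ids,
      cluster = cluster,
      doublet_flag = !is.na(planted_kind) & planted_kind == "doublet",
      n_heavy_chains = ifelse(!is.na(planted_kind) & planted_kind == "multi_chain", 2L, 1L),
      n_light_chains = 1L
    )
    m <- expression_matrix(counts, cell_meta = meta)

    list(
      matrix = m,
      truth = list(
        modules = tibble(gene = gene_names, true_module = module_of),
        cells = tibble(cell_id = cell_ids, true_cluster = cluster,
                       planted_failure = planted_kind)
      ),
      config = cfg
    )
  })
}
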