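#' Default run configuration
#'
#' Returns the pipeline's run configuration as a named list. The quality
#' control thresholds are the study conventions for droplet scRNA-seq of
#' primate gut leukocytes: cells with more than 10% mitochondrial reads,
#' fewer than 1200 UMIs or fewer than 500 detected genes are discarded, and
#' genes seen in fewer than 10 cells are dropped. Clonal lineages tolerate at
#' most a 20% nucleotide mismatch fraction between CDR3s sharing a V/J
#' allele and CDR3-length key.
#'
#' @param ... named overrides for any configuration field.
#'
#' @return A named list of class `clonetrace_config` with fields:
#' \describe{
#'   \item{mito_max_fraction}{cells above this mitochondrial read fraction
#'     are removed (strictly greater; default 0.10).}
#'   \item{min_umi}{cells with fewer total UMIs are removed (strict;
#'     default 1200).}
#'   \item{min_genes}{cells with fewer detected genes are removed (strict;
#'     default 500).}
#'   \item{min_cells_per_gene}{genes detected in fewer cells are removed
#'     (strict; default 10).}
#'   \item{hvg_count}{number of highly variable genes selected (default 3000).}
#'   \item{module_count}{number of gene modules cut from the topological
#'     overlap tree (default 100).}
#'   \item{adjacency_power}{soft-threshold exponent for the co-expression
#'     adjacency (default 6, the usual network convention).}
#'   \item{cdr3_mismatch_max_fraction}{maximum CDR3 nucleotide mismatch
#'     fraction joining two sequences into one lineage (inclusive;
#'     default 0.20).}
#'   \item{isotype_min_score}{minimum constant-region identity to call an
#'     isotype; below it the call is "unknown" (default 0.90).}
#'   \item{seed}{integer seed propagated to all stochastic components.}
#' }
#'
#' @examples
#' cfg <- default_config(seed = 7)
#' cfg$cdr3_mismatch_max_fraction
#' @export
default_config <- function(...) {
  cfg <- list(
    mito_max_fraction = 0.10,
    min_umi = 1200L,
    min_genes = 500L,
    min_cells_per_gene = 10L,
    hvg_count = 3000L,
    module_count = 100L,
    adjacency_power = 6,
    cdr3_mismatch_max_fraction = 0.20,
    isotype_min_score = 0.90,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = c("clonetrace_config", "list"))
}

validate_config <- function(cfg) {
  num_pos <- c(
    "mito_max_fraction", "min_umi", "min_genes", "min_cells_per_gene",
    "hvg_count", "module_count", "adjacency_power",
    "cdr3_mismatch_max_fraction", "isotype_min_score"
  )
  for (f in num_pos) {
    v <- cfg[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(paste0("config field '", f, "' must be a single positive number"))
    }
  }
  for (f in c("mito_max_fraction", "cdr3_mismatch_max_fraction", "isotype_min_score")) {
    if (cfg[[f]] > 1) abort(paste0("config field '", f, "' must lie in (0, 1]"))
  }
  invisible(cfg)
}

#' Read or write a run configuration (YAML)
#'
#' @param path path to a YAML file.
#' @return `read_config()` returns a validated `clonetrace_config` list;
#'   unspecified fields take their defaults.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' write_config(default_config(seed = 3), p)
#' read_config(p)$seed
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

#' @rdname read_config
#' @param cfg a configuration list from [default_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
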