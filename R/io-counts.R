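#' Construct an expression matrix container
#'
#' Bundles a sparse genes-by-cells count matrix with per-gene flags and
#' per-cell metadata. Per-cell totals (`total_umi`), detected gene counts and
#' mitochondrial read fractions are derived from the counts; supplied
#' metadata contributes `cluster`, `doublet_flag` and the immunoglobulin
#' chain counts used by quality control.
#'
#' @param counts genes-by-cells matrix of non-negative integer counts
#'   (coerced to `dgCMatrix`); rownames are gene names, colnames cell ids.
#' @param cell_meta optional tibble keyed by `cell_id` with any of
#'   `cluster`, `doublet_flag`, `n_heavy_chains`, `n_light_chains`.
#' @param mito_prefix gene-name prefix marking mitochondrially encoded genes
#'   (case-insensitive; default `"MT-"`).
#' @return An object of class `expr_matrix`: a list with `counts`
#'   (dgCMatrix), `genes` (tibble: gene, mito) and `cells` (tibble with the
#'   per-cell metadata and derived QC quantities).
#' @examples
#' m <- matrix(c(5, 0, 1, 2, 3, 0), nrow = 3,
#'             dimnames = list(c("MT-CO1", "CD3D", "MS4A1"), c("c1", "c2")))
#' em <- expression_matrix(m)
#' em$cells$mito_fraction
#' @export
expression_matrix <- function(counts, cell_meta = NULL, mito_prefix = "MT-") {
  if (!methods::is(counts, "Matrix")) {
    counts <- Matrix::Matrix(as.matrix(counts) * 1.0, sparse = TRUE)
  }
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must carry gene rownames and cell colnames")
  }
  if (any(counts@x < 0)) abort("counts must be non-negative")

  mito <- startsWith(toupper(rownames(counts)), toupper(mito_prefix))
  genes <- tibble(gene = rownames(counts), mito = mito)

  total_umi <- Matrix::colSums(counts)
  n_det <- Matrix::colSums(counts > 0)
  mito_umi <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else 0
  cells <- tibble(
    cell_id = colnames(counts),
    total_umi = as.numeric(total_umi),
    n_genes_detected = as.integer(n_det),
    mito_fraction = ifelse(total_umi > 0, mito_umi / total_umi, 0),
    doublet_flag = FALSE,
    n_heavy_chains = NA_integer_,
    n_light_chains = NA_integer_,
    cluster = NA_character_
  )
  if (!is.null(cell_meta)) {
    cell_meta <- as_tibble(cell_meta)
    if (!"cell_id" %in% names(cell_meta)) abort("cell_meta must have a cell_id column")
    extra <- intersect(
      c("cluster", "doublet_flag", "n_heavy_chains", "n_light_chains"),
      names(cell_meta)
    )
    cells <- cells[, setdiff(names(cells), extra)]
    cells <- left_join(cells, cell_meta[, c("cell_id", extra)], by = "cell_id")
  }
  structure(list(counts = counts, genes = genes, cells = cells),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts), " cells (",
      sum(x$genes$mito), " mitochondrial genes)\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' Read a sparse count matrix with name files and per-cell metadata
#'
#' Reads a MatrixMarket counts file plus one-gene-per-line and
#' one-cell-per-line name files, and an optional tab-separated per-cell
#' metadata table (`cell_id`, `cluster`, `doublet_flag`, `n_heavy_chains`,
#' `n_light_chains`).
#'
#' @param mtx_path MatrixMarket (.mtx) file, genes as rows.
#' @param genes_path text file of gene names, one per row-line.
#' @param cells_path text file of cell ids, one per column-line.
#' @param metadata_path optional per-cell metadata TSV.
#' @inheritParams expression_matrix
#' @return An `expr_matrix` (see [expression_matrix()]).
#' @export
read_counts <- function(mtx_path, genes_path, cells_path,
                        metadata_path = NULL, mito_prefix = "MT-") {
  for (p in c(mtx_path, genes_path, cells_path)) {
    if (!file.exists(p)) abort(paste0("counts input not found: ", p))
  }
  m <- Matrix::readMM(mtx_path)
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  if (nrow(m) != length(genes)) {
    abort(sprintf("matrix has %d rows but gene file lists %d names",
                  nrow(m), length(genes)))
  }
  if (ncol(m) != length(cells)) {
    abort(sprintf("matrix has %d columns but cell file lists %d names",
                  ncol(m), length(cells)))
  }
  dimnames(m) <- list(genes, cells)
  meta <- NULL
  if (!is.null(metadata_path)) {
    meta <- readr::read_tsv(metadata_path, show_col_types = FALSE, progress = FALSE)
    if ("doublet_flag" %in% names(meta)) {
      meta$doublet_flag <- as.logical(meta$doublet_flag)
    }
  }
  expression_matrix(m, cell_meta = meta, mito_prefix = mito_prefix)
}

#' Write an expression matrix as MTX plus name and metadata files
#'
#' Inverse of [read_counts()]; writes `counts.mtx`, `genes.txt`,
#' `cells.txt` and `cell_metadata.tsv` under `dir`.
#'
#' @param m an `expr_matrix`.
#' @param dir output directory (created if needed).
#' @export
write_counts <- function(m, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "counts.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "genes.txt"))
  writeLines(colnames(m$counts), file.path(dir, "cells.txt"))
  meta <- m$cells[, c("cell_id", "cluster", "doublet_flag",
                      "n_heavy_chains", "n_light_chains")]
  readr::write_tsv(meta, file.path(dir, "cell_metadata.tsv"), progress = FALSE)
  invisible(dir)
}
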