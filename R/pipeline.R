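#' Adjusted Rand index between inferred and true lineage partitions
#'
#' @param assigned lineage-annotated tibble with `sequence_id` and
#'   `lineage_id`.
#' @param truth tibble with `sequence_id` and `true_lineage_id`.
#' @return ARI in \[-1, 1\]; 1 means the partitions agree exactly.
#' @export
lineage_recovery_ari <- function(assigned, truth) {
  joined <- dplyr::inner_join(
    select(assigned, sequence_id, lineage_id),
    select(truth, sequence_id, true_lineage_id),
    by = "sequence_id"
  )
  if (!nrow(joined)) abort("no shared sequence ids between assignment and truth")
  mclust::adjustedRandIndex(joined$lineage_id, joined$true_lineage_id)
}

#' Run the full pipeline on a fixture-style input directory
#'
#' Chains the stages end to end: count QC (cell filters, gene prevalence),
#' normalization, HVG selection, network module detection and scoring,
#' per-cluster percent-deviance association, gene-set scoring; then
#' isotype assignment, lineage inference over combined single-cell and
#' bulk heavy chains, SHM annotation, cross-tissue tracing and the usage /
#' isotype / SHM summaries. All result tables are written as TSV under
#' `out_dir` along with a run manifest (config hash, input checksums,
#' package version, per-stage row counts, seed). If a `truth/` directory
#' is present the manifest also reports the lineage-recovery adjusted
#' Rand index.
#'
#' @param input_dir directory laid out as by [write_fixtures()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with every stage result and the manifest.
#' @examples
#' \donttest{
#' dir <- tempfile()
#' write_fixtures(dir, repertoire_config(n_lineages = 5, n_sequences = 50),
#'                expression_config(n_cells = 60))
#' res <- run_pipeline(dir, file.path(dir, "out"))
#' res$manifest$lineage_ari
#' }
#' @export
run_pipeline <- function(input_dir, out_dir = file.path(input_dir, "out")) {
  cfg_path <- file.path(input_dir, "config.yaml")
  if (!file.exists(cfg_path)) abort(paste0("missing config: ", cfg_path))
  cfg <- read_config(cfg_path)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_msg <- function(...) message("[clonetrace] ", sprintf(...))

  ## --- expression arm -----------------------------------------------------
  cdir <- file.path(input_dir, "counts")
  m <- read_counts(
    file.path(cdir, "counts.mtx"), file.path(cdir, "genes.txt"),
    file.path(cdir, "cells.txt"), file.path(cdir, "cell_metadata.tsv")
  )
  log_msg("counts: %d genes x %d cells", nrow(m$counts), ncol(m$counts))
  qc <- qc_filter_cells(m, cfg)
  log_msg("QC: %d cells retained", ncol(qc$matrix$counts))
  mg <- filter_genes(qc$matrix, cfg)
  log_msg("gene filter: %d genes retained", nrow(mg$counts))
  x <- normalize_log(mg)
  hvg <- select_hvg(x, n = min(cfg$hvg_count, nrow(x)))
  xh <- x[hvg, , drop = FALSE]
  adj <- build_adjacency(xh, power = cfg$adjacency_power)
  tom <- compute_tom(adj)
  modules <- cut_modules(tom, k = min(cfg$module_count, nrow(tom)))
  scores <- score_modules(xh, modules)
  assoc <- test_module_association(scores, mg$cells$cluster)
  gsets <- list(mito_oxphos = intersect(
    c(oxphos_mito_genes(), mg$genes$gene[mg$genes$mito]), rownames(x)
  ))
  gset_tab <- if (length(gsets$mito_oxphos)) {
    gene_set_score(x, gsets, mg$cells$cluster)
  } else {
    NULL
  }

  ## --- repertoire arm -----------------------------------------------------
  sc_path <- file.path(input_dir, "single_cell.tsv")
  if (!file.exists(sc_path)) abort(paste0("missing single-cell table: ", sc_path))
  records <- read_airr(sc_path)
  bulk_paths <- list.files(input_dir, pattern = "^bulk_.*\\.tsv$",
                           full.names = TRUE)
  for (bp in bulk_paths) records <- bind_rows(records, read_airr(bp))
  log_msg("repertoire: %d rearrangements (%d bulk tables)",
          nrow(records), length(bulk_paths))

  c_ref_path <- file.path(input_dir, "germline", "constant.fasta")
  if (file.exists(c_ref_path)) {
    records <- assign_isotypes(records, read_fasta(c_ref_path),
                               min_score = cfg$isotype_min_score)
  }
  assigned <- infer_lineages(records,
                             threshold = cfg$cdr3_mismatch_max_fraction)
  assigned <- add_shm_percent(assigned)
  log_msg("lineages: %d inferred", dplyr::n_distinct(assigned$lineage_id))

  lin_summary <- summarise_lineages(assigned)
  caecal_ids <- unique(assigned$lineage_id[assigned$source == "single_cell"])
  trace <- trace_lineages(assigned, lineage_ids = caecal_ids)
  shm_tab <- shm_by_compartment(assigned)
  usage <- vj_usage(assigned)
  cells <- pair_cells(records)
  iso <- isotype_composition(
    left_join(cells,
              select(assigned, sequence_id, isotype),
              by = c(heavy_sequence_id = "sequence_id"))
  )

  ## --- outputs + manifest -------------------------------------------------
  ow <- function(tab, name) {
    readr::write_tsv(tab, file.path(out_dir, name), progress = FALSE)
  }
  ow(qc$report, "qc_report.tsv")
  ow(modules, "module_membership.tsv")
  ow(as_tibble(t(scores), rownames = "cell_id"), "module_scores.tsv")
  ow(tidy(assoc), "module_association.tsv")
  if (!is.null(gset_tab)) ow(gset_tab, "gene_set_scores.tsv")
  ow(select(assigned, sequence_id, lineage_id, stage), "lineage_membership.tsv")
  ow(lin_summary, "lineage_summary.tsv")
  ow(trace, "trace_table.tsv")
  ow(shm_tab, "shm_by_compartment.tsv")
  ow(usage, "vj_usage.tsv")
  ow(iso, "isotype_composition.tsv")

  inputs <- c(cfg_path, sc_path, bulk_paths,
              file.path(cdir, c("counts.mtx", "genes.txt", "cells.txt",
                                "cell_metadata.tsv")))
  manifest <- list(
    tool_version = as.character(utils::packageVersion("clonetrace")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    stage_counts = list(
      cells_in = ncol(m$counts), cells_post_qc = ncol(qc$matrix$counts),
      genes_post_filter = nrow(mg$counts), hvgs = length(hvg),
      modules = dplyr::n_distinct(modules$module_id),
      rearrangements = nrow(records),
      heavy_chains = sum(records$locus == "IGH"),
      lineages = dplyr::n_distinct(assigned$lineage_id),
      paired_cells = nrow(cells)
    )
  )
  truth_path <- file.path(input_dir, "truth", "sequences.tsv")
  if (file.exists(truth_path)) {
    truth <- readr::read_tsv(truth_path, show_col_types = FALSE, progress = FALSE)
    manifest$lineage_ari <- lineage_recovery_ari(assigned, truth)
    log_msg("lineage recovery ARI vs truth: %.4f", manifest$lineage_ari)
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(
    qc = qc, filtered = mg, normalized = x, hvg = hvg, modules = modules,
    scores = scores, association = assoc, gene_sets = gset_tab,
    records = records, assigned = assigned, lineage_summary = lin_summary,
    trace = trace, shm = shm_tab, usage = usage, isotypes = iso,
    manifest = manifest
  ))
}
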