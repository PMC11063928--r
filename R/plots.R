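#' Plot a QC removal report
#'
#' Bar chart of cells removed per QC rule.
#'
#' @param report the `report` tibble from [qc_filter_cells()].
#' @return A ggplot object.
#' @export
plot_qc_report <- function(report) {
  dat <- filter(report, rule != "retained")
  ggplot2::ggplot(dat, ggplot2::aes(x = rule, y = n_removed)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "cells removed", title = "QC removals by rule") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Heatmap of module-cluster association statistics
#'
#' @param object a `module_association` from [test_module_association()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot module_association
#' @export
autoplot.module_association <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = cluster_id, y = module_id,
                               fill = percent_deviance_difference)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% deviance\nexplained",
                                  limits = c(0, 100)) +
    ggplot2::labs(x = "cluster", y = "gene module") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of isotype composition
#'
#' @param composition tibble from [isotype_composition()].
#' @return A ggplot object.
#' @export
plot_isotype_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = stats::reorder(isotype, -percentage),
                               y = percentage)) +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::labs(x = NULL, y = "% of paired antibodies") +
    ggplot2::theme_minimal()
}

#' Bar chart of heavy-chain V/J gene usage
#'
#' @param usage tibble from [vj_usage()].
#' @return A ggplot object faceted by segment class.
#' @export
plot_vj_usage <- function(usage) {
  ggplot2::ggplot(usage,
                  ggplot2::aes(x = stats::reorder(gene, -count), y = count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~segment, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "sequences") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1,
                                                       size = 6))
}

#' Lineage tracing tile plot
#'
#' Relative abundance of each traced lineage across compartments.
#'
#' @param trace tibble from [trace_lineages()].
#' @return A ggplot object.
#' @export
plot_lineage_trace <- function(trace) {
  ggplot2::ggplot(trace,
                  ggplot2::aes(x = tissue, y = lineage_id,
                               fill = relative_abundance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "relative\nabundance", trans = "sqrt") +
    ggplot2::labs(x = "compartment", y = "lineage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' SHM by compartment, quartile crossbars
#'
#' @param shm tibble from [shm_by_compartment()].
#' @return A ggplot object.
#' @export
plot_shm_by_compartment <- function(shm) {
  dat <- filter(shm, n > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = tissue, y = median_shm)) +
    ggplot2::geom_crossbar(ggplot2::aes(ymin = q25, ymax = q75),
                           fill = "grey80", width = 0.6) +
    ggplot2::labs(x = "compartment", y = "V-gene SHM (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
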