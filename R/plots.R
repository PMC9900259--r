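# ggplot2 views of the main result types. These return ggplot objects so
# callers can theme or facet further.

#' Plot a feature-category distribution
#'
#' @param dist A [feature_distribution()] tibble.
#' @return A ggplot bar chart of category percentages.
#' @export
plot_feature_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(
    x = factor(.data$feature, levels = FEATURE_LEVELS),
    y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "% of regions",
                  title = "Genomic distribution of eccDNA regions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a coverage profile
#'
#' @param profile A [linear_profile()] / [circular_profile()] tibble (or
#'   several row-bound together; facets by `mode`).
#' @return A ggplot of per-bin counts per cluster.
#' @export
plot_coverage_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(
    x = (.data$bin_start + .data$bin_end) / 2, y = .data$count,
    colour = .data$cluster_id)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~mode, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = "reads per bin",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot a region-by-class cCRE overlap table as a heatmap
#'
#' @param table A [cre_overlap_matrix()] tibble.
#' @return A ggplot tile heatmap of overlap counts.
#' @export
plot_cre_overlap <- function(table) {
  long <- tidyr::pivot_longer(table, -"region_id",
                              names_to = "cre_class", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$cre_class, levels = CRE_CLASSES),
    y = .data$region_id, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "cCRE class", y = NULL, fill = "overlaps") +
    ggplot2::theme_minimal()
}

#' Plot per-group eccDNA-harboring fractions
#'
#' @param hf A [harboring_fraction()] tibble.
#' @return A ggplot bar chart of percentages per group.
#' @export
plot_harboring_fraction <- function(hf) {
  ggplot2::ggplot(hf, ggplot2::aes(x = .data$group, y = .data$fraction)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "% cells harboring eccDNA") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot per-cell circular signal by group
#'
#' @param signal A [per_cell_signal()] tibble.
#' @param group Grouping column name (default `"cluster_id"`).
#' @return A ggplot box/jitter plot of per-cell values.
#' @export
plot_per_cell_signal <- function(signal, group = "cluster_id") {
  ggplot2::ggplot(signal, ggplot2::aes(
    x = .data[[group]], y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = NULL, y = "circle-supporting reads per cell") +
    ggplot2::theme_minimal()
}
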