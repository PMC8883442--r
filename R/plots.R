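#' Histogram of per-condition defect counts, by strain
#'
#' Visualises the bimodality that motivates the QC exclusion threshold: a
#' low mode of kinase-specific conditions and a high mode of globally toxic
#' ones, with the cutoff drawn as a vertical line.
#'
#' @param counts Tibble from [defect_counts()].
#' @param threshold Exclusion cutoff to draw (default 175).
#' @param bin_width Histogram bin width.
#' @return A ggplot object.
#' @export
plot_defect_counts <- function(counts, threshold = 175, bin_width = 10) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$n_defect)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$strain)) +
    ggplot2::labs(x = "kinases with growth defect per condition",
                  y = "conditions") +
    ggplot2::theme_minimal()
}

#' @describeIn cluster_tiers Heat-map of bin profiles in dendrogram order,
#'   annotated with the assigned activity tier.
#' @param object A `tier_clustering` object.
#' @method autoplot tier_clustering
#' @export
autoplot.tier_clustering <- function(object, ...) {
  ord <- rownames(object$bin_matrix)[object$hclust$order]
  long <- as_tibble(object$bin_matrix, rownames = "protein_id") %>%
    tidyr::pivot_longer(-"protein_id", names_to = "strain",
                        values_to = "bin") %>%
    left_join(object$tiers, by = "protein_id") %>%
    mutate(protein_id = factor(.data$protein_id, levels = ord))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strain, y = .data$protein_id,
                                     fill = .data$bin)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$tier), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 4)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "bin (0-4)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Box plots of per-condition-strain phenotype fractions by group
#'
#' @param fractions Tibble from [group_fractions()].
#' @return A ggplot object.
#' @export
plot_group_fractions <- function(fractions) {
  ggplot2::ggplot(fractions, ggplot2::aes(x = .data$group, y = .data$fraction)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = NULL,
                  y = "fraction of group with phenotype (per condition-strain)") +
    ggplot2::theme_minimal()
}

#' Bar chart of upset combination counts
#'
#' @param counts Tibble from [upset_counts()].
#' @return A ggplot object.
#' @export
plot_upset_counts <- function(counts) {
  counts <- mutate(counts, combination = stats::reorder(.data$combination,
                                                        -.data$count))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$combination, y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "strain combination (exact membership)",
                  y = "kinase-condition pairs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn fit_logistic Observed points with the fitted logistic curve.
#' @param object A `logistic_fit` object.
#' @method autoplot logistic_fit
#' @export
autoplot.logistic_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(time_h = seq(min(d$time_h), max(d$time_h), length.out = 200))
  grid$od <- object$baseline +
    (object$K - object$baseline) / (1 + exp(-object$r * (grid$time_h - object$t0)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$od)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "time (h)", y = "OD595") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
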