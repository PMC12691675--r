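#' Plot a distance space with its target partition
#'
#' Scatter of the standardized (phylogenetic, protein) distance plane, the
#' target species' pair-points highlighted against the background cloud.
#'
#' @param object a [distance_space()].
#' @param target target species label (colors the in-cluster points).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot distance_space
#' @export
autoplot.distance_space <- function(object, target = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(target)) {
    part <- partition_points(object, target)
    df$cluster <- "other pairs"
    df$cluster[part$in_cluster] <- paste("pairs with", target)
  } else {
    df$cluster <- "pairs"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$cluster)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "standardized 16S distance",
                  y = "standardized protein distance", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot gene PD scores with the z-score threshold
#'
#' @param scores a [score_genes()] table.
#' @return a ggplot of the ranked PD distribution, flagged genes highlighted.
#' @export
plot_gene_scores <- function(scores) {
  ggplot2::ggplot(scores,
                  ggplot2::aes(.data$rank_pd, .data$pd,
                               colour = .data$above_threshold)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "PD rank", y = "PD score",
                  colour = paste0("z ≥ ",
                                  attr(scores, "z_threshold"))) +
    ggplot2::theme_minimal()
}

#' Plot a per-site selection profile
#'
#' Two panels in one frame: per-codon dN/dS with the neutral threshold and
#' detected runs, and per-column amino-acid divergence with flagged sites.
#'
#' @param profile the `profile` tibble from [selection_profile()].
#' @param threshold neutral line (default 1).
#' @return a ggplot.
#' @export
plot_site_profile <- function(profile, threshold = 1) {
  long <- tidyr::pivot_longer(profile, c("dnds", "divergence"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, c("dnds", "divergence"),
                        c("dN/dS per codon", "aa divergence"))
  hl <- tibble::tibble(metric = factor("dN/dS per codon",
                                       levels(long$metric)),
                       y = threshold)
  ggplot2::ggplot(long, ggplot2::aes(.data$codon_column, .data$value)) +
    ggplot2::geom_hline(data = hl, ggplot2::aes(yintercept = .data$y),
                        colour = "red", linetype = 2) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$in_run), width = 1) +
    ggplot2::geom_point(
      data = dplyr::filter(long, .data$flagged,
                           .data$metric == "aa divergence"),
      colour = "red", size = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey50",
                                          `TRUE` = "steelblue"),
                               guide = "none") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "codon column", y = NULL) +
    ggplot2::theme_minimal()
}
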