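#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_step facet_wrap labs scale_fill_gradient2 theme_minimal
NULL

#' Heatmap of a covariance network's correlation matrix
#'
#' @param object A `covariance_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot covariance_network
#' @export
autoplot.covariance_network <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$region_a, y = .data$region_b, fill = .data$r)) +
    geom_tile() +
    geom_tile(aes(x = .data$region_b, y = .data$region_a)) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Pearson r",
         title = object$group %||% "Metabolic covariance network") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Heatmap of surviving signed edges of a thresholded network
#'
#' @param object A `thresholded_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot thresholded_network
#' @export
autoplot.thresholded_network <- function(object, ...) {
  adj <- object$adjacency
  idx <- which(upper.tri(adj), arr.ind = TRUE)
  df <- tibble::tibble(region_a = object$regions[idx[, 1L]],
                       region_b = object$regions[idx[, 2L]],
                       weight = adj[idx])
  ggplot(df, aes(x = .data$region_a, y = .data$region_b,
                 fill = .data$weight)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "edge weight",
         title = sprintf("Surviving edges (alpha = %g, density %.2f)",
                         object$alpha, object$density)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Co-classification heatmap of an MRCC consensus
#'
#' Regions ordered by consensus community; block structure indicates a
#' stable partition.
#'
#' @param object An `mrcc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mrcc_result
#' @export
autoplot.mrcc_result <- function(object, ...) {
  ord <- order(object$partition$community)
  regs <- object$partition$region[ord]
  a <- object$coclassification[regs, regs]
  df <- tidyr::expand_grid(region_a = factor(regs, levels = regs),
                           region_b = factor(regs, levels = regs))
  df$value <- as.vector(a[as.matrix(df)])
  ggplot(df, aes(x = .data$region_a, y = .data$region_b,
                 fill = .data$value)) +
    geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "co-classification",
         title = sprintf("MRCC consensus: %d communities", object$k)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Concentration-time profiles on a log scale
#'
#' @param profiles Tibble from [generate_pk_profiles()].
#' @return A ggplot faceted by dose.
#' @export
plot_concentration_profiles <- function(profiles) {
  ggplot(dplyr::filter(profiles, .data$conc_ng_per_ml > 0),
         aes(x = .data$time_h, y = .data$conc_ng_per_ml,
             group = .data$animal_id, colour = .data$sex)) +
    geom_line(alpha = 0.6) + geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    facet_wrap(~dose_mg_per_kg, labeller = ggplot2::label_both) +
    labs(x = "time (h)", y = "plasma concentration (ng/mL)") +
    theme_minimal()
}

#' Empirical CDFs of a nodal metric across groups
#'
#' The visual companion of the two-sample KS comparisons: step ECDFs of a
#' nodal metric's global distribution for each group.
#'
#' @param metrics Tidy nodal-metric table (from [group_networks()]).
#' @param metric Which metric column to plot.
#' @return A ggplot.
#' @export
plot_metric_ecdf <- function(metrics, metric = "degree") {
  df <- dplyr::mutate(metrics,
                      group = paste(.data$sex, .data$genotype,
                                    .data$treatment, sep = "_"))
  ggplot(df, aes(x = .data[[metric]], colour = .data$group)) +
    ggplot2::stat_ecdf(geom = "step") +
    labs(x = metric, y = "empirical CDF") +
    theme_minimal()
}

#' Delta-from-vehicle heat map
#'
#' @param deltas Tibble from [delta_from_vehicle()].
#' @return A ggplot.
#' @export
plot_delta_heatmap <- function(deltas) {
  ggplot(dplyr::filter(deltas, !is.na(.data$delta)),
         aes(x = .data$treatment, y = .data$gene, fill = .data$delta)) +
    geom_tile() +
    scale_fill_gradient2() +
    facet_wrap(~sex) +
    labs(x = "treatment", y = NULL, fill = "delta log2") +
    theme_minimal()
}
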