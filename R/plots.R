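# Cosmetic plot methods (heatmap, importance boxplots).  Untested surface:
# figures summarize the same tidy tables the tests cover.

#' Heatmap of the position-by-feature matrix
#'
#' @param object A `zp_feature_matrix`.
#' @param boundary_index Optional boundary row to mark with a dashed line.
#' @param ... Unused.
#' @return A ggplot object (tip at the top, features ordered as assembled).
#' @exportS3Method ggplot2::autoplot
autoplot.zp_feature_matrix <- function(object, boundary_index = NULL, ...) {
  d <- as_tibble(as.data.frame(as.table(object$values), stringsAsFactors = FALSE))
  names(d) <- c("position", "feature", "intensity")
  d$position <- as.integer(factor(d$position, levels = unique(d$position)))
  d$feature <- factor(d$feature, levels = colnames(object$values))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$feature, .data$position,
                                       fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "feature (probe x replicate x time point)",
                  y = "axial position (1 = tip)", fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(boundary_index)) {
    p <- p + ggplot2::geom_hline(yintercept = boundary_index + 0.5,
                                 linetype = "dashed", colour = "white")
  }
  p
}

#' Plot a compartmentalization result
#'
#' @param object A `zp_compartment`.
#' @param ... Unused.
#' @return Feature-matrix heatmap with the apical/basal boundary marked.
#' @exportS3Method ggplot2::autoplot
autoplot.zp_compartment <- function(object, ...) {
  autoplot(object$feature_matrix,
           boundary_index = object$boundary$boundary_index)
}

#' Boxplot of per-structure Gini importance
#'
#' One box per probe over its per-replicate aggregated mean-decrease-Gini
#' values (percent of total), mirroring the importance comparison across
#' intracellular structures.
#'
#' @param object A `zp_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.zp_classification <- function(object, ...) {
  d <- object$importance_by_structure
  ggplot2::ggplot(d, ggplot2::aes(.data$probe, .data$mean_decrease_gini_pct)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "mean decrease in Gini (%)") +
    ggplot2::theme_classic()
}

#' Plot normalized axial profiles
#'
#' @param profiles Long profile tibble from [extract_profiles()].
#' @return A ggplot object, one panel per probe, colour by time point.
#' @export
plot_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(.data$position, .data$intensity,
                               colour = .data$timepoint,
                               group = interaction(.data$replicate_id,
                                                   .data$timepoint))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~probe) +
    ggplot2::labs(x = "axial position (1 = tip)",
                  y = "normalized intensity (z-score)",
                  colour = "T") +
    ggplot2::theme_minimal()
}
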