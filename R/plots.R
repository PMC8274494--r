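#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the applicability domain as a PCA scores plot
#'
#' Internal-set scores with the bounding box; optionally overlays query or
#' external-set scores coloured by domain membership.
#'
#' @param object An `erq_domain`.
#' @param query Optional feature-matrix tibble to project and overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.erq_domain <- function(object, query = NULL, ...) {
  sc <- object$internal_scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::annotate("rect",
      xmin = object$box$lo[1], xmax = object$box$hi[1],
      ymin = object$box$lo[min(2, nrow(object$box))],
      ymax = object$box$hi[min(2, nrow(object$box))],
      alpha = 0.08, fill = "steelblue"
    ) +
    ggplot2::geom_point(colour = "firebrick", alpha = 0.6) +
    ggplot2::labs(
      x = "PC1", y = "PC2",
      title = "PCA bounding-box applicability domain",
      subtitle = "internal set (red); box = per-component score range"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(query)) {
    qs <- in_domain(object, query)
    p <- p + ggplot2::geom_point(
      data = qs,
      ggplot2::aes(x = .data$PC1, y = .data$PC2, shape = .data$in_domain),
      colour = "navy", alpha = 0.7
    )
  }
  p
}

#' Plot feature importances of a fitted classifier
#'
#' Horizontal bar chart of the top mean-decrease-Gini features.
#'
#' @param object An `erq_rf_model`.
#' @param top_k How many features to show (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.erq_rf_model <- function(object, top_k = 20, ...) {
  imp <- rank_features(object, top_k = top_k)
  ggplot2::ggplot(
    imp,
    ggplot2::aes(
      x = .data$mdgi,
      y = stats::reorder(.data$feature_name, .data$mdgi)
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "mean decrease of the Gini index", y = NULL,
      title = sprintf("Top %d features by MDGI", nrow(imp))
    ) +
    ggplot2::theme_minimal()
}

#' Box plots of rule-of-five descriptors by activity class
#'
#' The chemical-space comparison view: one panel per Ro5 descriptor,
#' classes side by side.
#'
#' @param profiles Tibble from [ro5_profile()] with a `label` column.
#' @return A ggplot.
#' @export
plot_ro5_by_class <- function(profiles) {
  long <- tidyr::pivot_longer(
    profiles[c("label", "mw", "alogp", "n_hbd", "n_hba")],
    cols = -"label", names_to = "descriptor", values_to = "value"
  )
  ggplot2::ggplot(
    long, ggplot2::aes(x = .data$label, y = .data$value, fill = .data$label)
  ) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~descriptor, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Ro5 descriptors by class") +
    ggplot2::theme_minimal()
}
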