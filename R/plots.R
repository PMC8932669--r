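#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an outline
#'
#' @param object A `jaw_outline`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot jaw_outline
#' @export
autoplot.jaw_outline <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(fill = "grey85", colour = "grey20",
                          linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot the empirical morphospace
#'
#' Specimen scores on PC1-PC2, coloured by clade when a `clade` column can
#' be joined.
#'
#' @param object A `shape_space`.
#' @param taxa Optional tibble with `taxon_id` and `clade`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot shape_space
#' @export
autoplot.shape_space <- function(object, taxa = NULL, ...) {
  sc <- object$scores
  if (!is.null(taxa) && "clade" %in% names(taxa)) {
    sc <- dplyr::left_join(sc, taxa[, c("taxon_id", "clade")], by = "taxon_id")
    p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = .data$clade))
  } else {
    p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot the adaptive landscape
#'
#' Pareto rank as a filled raster over PC1-PC2; invalid (self-intersecting)
#' regions stay blank. A phylomorphospace can be superimposed.
#'
#' @param object An `adaptive_landscape`.
#' @param phylo Optional `phylomorphospace` to overlay.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot adaptive_landscape
#' @export
autoplot.adaptive_landscape <- function(object, phylo = NULL, ...) {
  p <- ggplot2::ggplot(object$nodes,
                       ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$rank)) +
    ggplot2::scale_fill_viridis_c(option = "mako", na.value = "grey70",
                                  limits = c(0, 1), name = "Pareto rank") +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
  if (!is.null(phylo)) {
    p <- p +
      ggplot2::geom_segment(
        data = phylo$edges,
        ggplot2::aes(x = .data$pc1, y = .data$pc2,
                     xend = .data$pc1_end, yend = .data$pc2_end),
        colour = "white", linewidth = 0.2
      ) +
      ggplot2::geom_point(
        data = dplyr::filter(phylo$vertices, .data$type == "tip"),
        ggplot2::aes(x = .data$pc1, y = .data$pc2),
        colour = "white", size = 0.8
      )
  }
  p
}

#' Plot a performance surface
#'
#' @param perf A performance table from [grid_performance()].
#' @param metric Column to plot (default `"re_mean"`).
#' @return A ggplot.
#' @export
plot_performance_surface <- function(perf, metric = "re_mean") {
  ggplot2::ggplot(perf, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data[[metric]])) +
    ggplot2::scale_fill_viridis_c(name = metric) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' Plot disparity and optimality through time
#'
#' One panel per metric, bins ordered old to young, with bootstrap 95%
#' intervals.
#'
#' @param dtt A table from [disparity_through_time()].
#' @return A ggplot.
#' @export
plot_disparity_through_time <- function(dtt) {
  long <- dplyr::bind_rows(
    tibble::tibble(bin = dtt$bin, metric = "sum of variances",
                   value = dtt$sov, lo = dtt$sov_ci_low,
                   hi = dtt$sov_ci_high),
    tibble::tibble(bin = dtt$bin, metric = "mean pairwise distance",
                   value = dtt$mpd, lo = dtt$mpd_ci_low,
                   hi = dtt$mpd_ci_high)
  )
  if ("mean_optimality" %in% names(dtt)) {
    long <- dplyr::bind_rows(
      long,
      tibble::tibble(bin = dtt$bin, metric = "mean optimality",
                     value = dtt$mean_optimality, lo = dtt$opt_ci_low,
                     hi = dtt$opt_ci_high)
    )
  }
  long$bin <- factor(long$bin, levels = unique(dtt$bin))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$value,
                                     group = 1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point(shape = 21, fill = "white") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
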