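#' @method autoplot vessel_heatmap
#' @export
autoplot.vessel_heatmap <- function(object, ...) {
  t_ <- dplyr::filter(object$tiles, .data$valid)
  ggplot2::ggplot(t_, ggplot2::aes(.data$x0_um, .data$y0_um,
                                   fill = .data$area_fraction)) +
    ggplot2::geom_tile(width = object$tile_um, height = object$tile_um) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                  name = "area\nfraction") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("Vascular area fraction, %.0f µm tiles",
                                  object$tile_um)) +
    ggplot2::theme_minimal()
}

#' Histogram of heatmap tile values
#'
#' @param heatmap A [vessel_heatmap()] result.
#' @return A ggplot of the 20-bin tile-value histogram.
#' @export
plot_heatmap_histogram <- function(heatmap) {
  stopifnot(inherits(heatmap, "vessel_heatmap"))
  ggplot2::ggplot(heatmap$histogram,
                  ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = 0.05, fill = "grey30") +
    ggplot2::labs(x = "tile area fraction", y = "tiles") +
    ggplot2::theme_minimal()
}

#' @method autoplot plexus_comparison
#' @export
autoplot.plexus_comparison <- function(object, ...) {
  d <- tidyr::pivot_longer(object$deviations, c("whole", "single"),
                           names_to = "analysis", values_to = "value")
  d$analysis <- factor(d$analysis, levels = c("whole", "single"),
                       labels = c("whole retina", "single plexus"))
  ggplot2::ggplot(d, ggplot2::aes(.data$parameter, .data$value,
                                  fill = .data$analysis)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~parameter, scales = "free", nrow = 1) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Whole-retina vs single-plexus analysis") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @method autoplot vessel_graph
#' @export
autoplot.vessel_graph <- function(object, ...) {
  segs <- purrr::imap_dfr(object$edges$polyline, function(p, i) {
    tibble::tibble(edge_id = i,
                   x = p[-nrow(p), 1], y = p[-nrow(p), 2],
                   xend = p[-1, 1], yend = p[-1, 2],
                   radius = object$edges$radius_um[i])
  })
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$radius),
                          lineend = "round", colour = "darkred") +
    ggplot2::scale_linewidth_continuous(range = c(0.3, 1.5), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Skeleton overlay plot
#'
#' Draws the classified skeleton pixels (slab, junction, endpoint) of a
#' skeleton graph, a quick visual check of the traced topology.
#'
#' @param graph A [build_graph()] result.
#' @return A ggplot.
#' @export
plot_skeleton <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  ggplot2::ggplot(graph$pixels,
                  ggplot2::aes(.data$x, .data$y, colour = .data$class)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = c(endpoint = "dodgerblue",
                                            slab = "grey40",
                                            junction = "red")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = NULL) +
    ggplot2::theme_minimal()
}
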