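# ggplot2 views of scenes, null comparisons and censuses.

#' Plot an x-y map of a marrow scene
#'
#' Vessels as ribbons (line width scaled to radius), megakaryocytes and
#' any highlighted cell types as points; the dense background pool is
#' omitted by default.
#'
#' @param cells cell table.
#' @param vessels a [vessel_network()] (optional).
#' @param highlight cell types to draw (default: everything except the
#'   background pool).
#' @return a ggplot object.
#' @export
plot_marrow_map <- function(cells, vessels = NULL,
                            highlight = setdiff(unique(cells$cell_type), "BM")) {
  p <- ggplot2::ggplot()
  if (!is.null(vessels) && nrow(tibble::as_tibble(vessels))) {
    vd <- tibble::as_tibble(vessels)
    p <- p + ggplot2::geom_path(
      data = vd,
      ggplot2::aes(x = .data$x_um, y = .data$y_um, group = .data$segment_id,
                   linewidth = .data$radius_um, colour = .data$vclass),
      alpha = 0.5) +
      ggplot2::scale_linewidth(range = c(0.5, 3), guide = "none") +
      ggplot2::scale_colour_manual(values = c(sinusoid = "#9ecae1",
                                              arteriole = "#fc9272"))
  }
  cd <- cells[cells$cell_type %in% highlight, , drop = FALSE]
  p +
    ggplot2::geom_point(data = cd,
                        ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                     size = .data$radius_um, fill = .data$cell_type),
                        shape = 21, alpha = 0.8) +
    ggplot2::scale_size(range = c(0.5, 4), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "cell type",
                  colour = "vessel") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.synthetic_marrow <- function(object, ...) {
  plot_marrow_map(object$cells, object$vessels, ...)
}

#' Plot an observed distance set against its empirical null
#'
#' Histogram of pooled null gap distances with the observed median (solid
#' line) and null median (dashed) marked.
#'
#' @param observed distance tibble with `gap_um` or numeric vector.
#' @param null a [null_distances()] object.
#' @return a ggplot object.
#' @export
plot_null_comparison <- function(observed, null) {
  obs <- if (is.numeric(observed)) observed else observed$gap_um
  ggplot2::ggplot(null$samples, ggplot2::aes(x = .data$gap_um)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey80", colour = "grey50") +
    ggplot2::geom_vline(xintercept = stats::median(obs), colour = "#de2d26",
                        linewidth = 1) +
    ggplot2::geom_vline(xintercept = stats::median(null$samples$gap_um),
                        linetype = "dashed") +
    ggplot2::labs(x = "gap distance (µm)", y = "null count",
                  title = paste0("observed vs random-placement null (",
                                 null$target, ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.null_distribution <- function(object, ...) {
  ggplot2::ggplot(object$medians, ggplot2::aes(x = .data$median_um)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey80", colour = "grey50") +
    ggplot2::labs(x = "replicate median gap (µm)", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Plot a production-site census
#'
#' @param census tibble from [site_census()].
#' @return a ggplot object.
#' @export
plot_site_census <- function(census) {
  ggplot2::ggplot(census, ggplot2::aes(x = .data$lineage,
                                       y = .data$density_per_mm2,
                                       fill = .data$lineage)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "production sites per mm²") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
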