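#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' types: point patterns as dot maps, synthetic scenes as channel rasters
#' with ground-truth overlays, cluster sets as footprints coloured by
#' cluster.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name astrospat-autoplot
NULL

#' @rdname astrospat-autoplot
#' @method autoplot point_pattern
#' @export
autoplot.point_pattern <- function(object, ...) {
  w <- pp_window(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::coord_fixed(xlim = c(0, w[1]), ylim = c(w[2], 0), expand = FALSE) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @rdname astrospat-autoplot
#' @param channel Channel name for scene plots.
#' @method autoplot synthetic_scene
#' @export
autoplot.synthetic_scene <- function(object, channel = "marker_a", ...) {
  img <- object$channels[[channel]]
  ps <- object$spec$pixel_size_um
  df <- tibble(
    x_um = rep((seq_len(ncol(img)) - 0.5) * ps, each = nrow(img)),
    y_um = rep((seq_len(nrow(img)) - 0.5) * ps, times = ncol(img)),
    value = as.vector(img))
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "green",
                                 limits = c(0, 255)) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = channel) +
    ggplot2::theme_minimal()
}

#' @rdname astrospat-autoplot
#' @method autoplot cluster_set
#' @export
autoplot.cluster_set <- function(object, ...) {
  m <- object$cluster_mask
  ps <- object$pixel_size_um
  idx <- which(m > 0)
  df <- tibble(
    x_um = (((idx - 1) %/% nrow(m)) + 0.5) * ps,
    y_um = (((idx - 1) %% nrow(m)) + 0.5) * ps,
    cluster = factor(m[idx]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$cluster)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
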