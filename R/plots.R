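surface_plot <- function(obj, fill_lab, diverging = FALSE) {
  df <- tidy(obj)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = "axis 1", y = "axis 2", fill = fill_lab) +
    ggplot2::theme_minimal()
  if (diverging) {
    p <- p + ggplot2::scale_fill_gradient2(low = "#276419", mid = "white",
                                           high = "#8e0152", midpoint = 0)
  } else {
    p <- p + ggplot2::scale_fill_viridis_c()
  }
  p
}

#' Plot a kriged performance surface
#'
#' @param object the surface/landscape object.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot performance_surface
#' @export
autoplot.performance_surface <- function(object, ...) {
  surface_plot(object, object$trait_name) +
    ggplot2::geom_point(
      data = tibble::tibble(x = object$points[, 1], y = object$points[, 2]),
      ggplot2::aes(.data$x, .data$y), inherit.aes = FALSE,
      shape = 21, fill = "white", size = 1.2
    )
}

#' @rdname autoplot.performance_surface
#' @method autoplot adaptive_landscape
#' @export
autoplot.adaptive_landscape <- function(object, ...) {
  p <- surface_plot(object, "height")
  if (is.numeric(object$focal)) {
    p <- p + ggplot2::annotate("point", x = object$focal[1], y = object$focal[2],
                               shape = 4, size = 3, colour = "white")
  }
  p
}

#' @rdname autoplot.performance_surface
#' @method autoplot transitional_landscape
#' @export
autoplot.transitional_landscape <- function(object, ...) {
  surface_plot(object, "parasagittal - sprawling", diverging = TRUE)
}

#' @rdname autoplot.performance_surface
#' @method autoplot pareto_landscape
#' @export
autoplot.pareto_landscape <- function(object, ...) {
  surface_plot(object, "Pareto optimality")
}

#' Scatterplot of a morphospace
#'
#' @param object a `morphospace`.
#' @param ... unused.
#' @return A ggplot of the first two axes, coloured by group when available.
#' @method autoplot morphospace
#' @export
autoplot.morphospace <- function(object, ...) {
  df <- object$scores
  ve <- object$var_explained
  lab <- function(i) {
    if (length(ve) >= i) sprintf("axis %d (%.1f%%)", i, 100 * ve[i]) else sprintf("axis %d", i)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2))
  p <- if (all(is.na(df$group))) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  p + ggplot2::labs(x = lab(1), y = lab(2)) + ggplot2::theme_minimal()
}

#' @rdname autoplot.morphospace
#' @export
plot_morphospace <- function(object, ...) autoplot.morphospace(object, ...)
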