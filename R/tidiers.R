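#' Tidy a fitted evolutionary model
#'
#' @param x an `evo_fit` from [fit_model()].
#' @param ... unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy evo_fit
#' @export
tidy.evo_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = unname(unlist(x$params)))
}

#' @rdname tidy.evo_fit
#' @return `glance()` returns a one-row model summary.
#' @method glance evo_fit
#' @export
glance.evo_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$loglik, n_params = x$n_params,
                 AIC = x$AIC, AICc = x$AICc, n_tips = x$n)
}

#' Tidy a morphospace
#'
#' @param x a `morphospace`.
#' @param ... unused.
#' @return The per-specimen score tibble.
#' @method tidy morphospace
#' @export
tidy.morphospace <- function(x, ...) x$scores

#' @rdname tidy.morphospace
#' @method glance morphospace
#' @export
glance.morphospace <- function(x, ...) {
  tibble::tibble(method = x$method, n_specimens = nrow(x$scores),
                 n_axes = ncol(x$all_scores),
                 var_axis1 = x$var_explained[1],
                 var_axis2 = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_)
}

#' Tidy gridded landscapes into long tibbles
#'
#' @param x a `performance_surface`, `adaptive_landscape`,
#'   `transitional_landscape` or `pareto_landscape`.
#' @param ... unused.
#' @return A tibble `x`, `y`, `value` (plus `R_O`, `R_S` for Pareto
#'   landscapes).
#' @method tidy performance_surface
#' @export
tidy.performance_surface <- function(x, ...) grid_tibble(x$grid, x$values)

#' @rdname tidy.performance_surface
#' @method tidy adaptive_landscape
#' @export
tidy.adaptive_landscape <- function(x, ...) grid_tibble(x$grid, x$values)

#' @rdname tidy.performance_surface
#' @method tidy transitional_landscape
#' @export
tidy.transitional_landscape <- function(x, ...) grid_tibble(x$grid, x$values)

#' @rdname tidy.performance_surface
#' @method tidy pareto_landscape
#' @export
tidy.pareto_landscape <- function(x, ...) {
  out <- grid_tibble(x$grid, x$score)
  out$R_O <- as.vector(x$R_O)
  out$R_S <- as.vector(x$R_S)
  out
}

grid_tibble <- function(grid, values) {
  tibble::tibble(
    x = rep(grid$x, times = grid$n_y),
    y = rep(grid$y, each = grid$n_x),
    value = as.vector(values)
  )
}
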