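#' Define an interpolation grid over morphospace
#'
#' @param scores a two-column matrix / data frame of morphospace coordinates
#'   (or a `morphospace` object, whose first two axes are used).
#' @param n_x,n_y grid resolution (>= 10).
#' @param pad_frac padding of the specimen bounding box on each side.
#' @return An object of class `grid_spec` with node coordinate vectors `x`,
#'   `y` and the ranges.
#' @export
grid_spec <- function(scores, n_x = 100, n_y = 100, pad_frac = 0.05) {
  xy <- score_xy(scores)
  if (n_x < 10 || n_y < 10) stop("grid resolution must be >= 10")
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  xr <- xr + c(-1, 1) * pad_frac * diff(xr)
  yr <- yr + c(-1, 1) * pad_frac * diff(yr)
  structure(
    list(x = seq(xr[1], xr[2], length.out = n_x),
         y = seq(yr[1], yr[2], length.out = n_y),
         x_range = xr, y_range = yr, n_x = n_x, n_y = n_y),
    class = "grid_spec"
  )
}

score_xy <- function(scores) {
  if (inherits(scores, "morphospace")) {
    return(as.matrix(scores$scores[, c("axis1", "axis2")]))
  }
  m <- as.matrix(as.data.frame(scores)[, 1:2])
  storage.mode(m) <- "double"
  m
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$x, b$x)) && isTRUE(all.equal(a$y, b$y))
}

#' Fit an empirical semivariogram
#'
#' Bins squared half-differences of the values by pair distance (default 12
#' lags to half the maximum inter-point distance) and fits the chosen model by
#' weighted least squares (weights N/h^2).
#'
#' @param points two-column coordinate matrix (>= 10 rows).
#' @param values numeric vector of observations.
#' @param model variogram model (`"spherical"`, `"exponential"` or
#'   `"gaussian"`).
#' @param nugget fixed nugget (default 0, giving exact interpolation).
#' @param n_bins number of distance bins.
#' @return A list of class `variogram_fit`: `model`, `nugget`, `psill`,
#'   `range`, and the `empirical` bin tibble.
#' @export
fit_variogram <- function(points, values, model = c("spherical", "exponential", "gaussian"),
                          nugget = 0, n_bins = 12) {
  model <- match.arg(model)
  pts <- score_xy(points)
  if (nrow(pts) < 10) stop("need >= 10 points to fit a variogram")
  d <- as.vector(stats::dist(pts))
  g <- as.vector(stats::dist(values))^2 / 2
  maxd <- max(d) / 2
  bins <- cut(d, breaks = seq(0, maxd, length.out = n_bins + 1), labels = FALSE)
  ok <- !is.na(bins)
  emp <- tibble::tibble(
    h = tapply(d[ok], bins[ok], mean),
    gamma = tapply(g[ok], bins[ok], mean),
    n = as.integer(table(bins[ok]))
  )
  if (stats::var(values) == 0) {
    warning("constant values: flat variogram")
    return(structure(list(model = model, nugget = nugget, psill = 0,
                          range = maxd, empirical = emp),
                     class = "variogram_fit"))
  }
  obj <- function(par) {
    ps <- exp(par[1]); rg <- exp(par[2])
    gm <- variogram_value(ps, rg, nugget, model, emp$h)
    sum(emp$n * (emp$gamma - gm)^2 / pmax(emp$h, 1e-12)^2)
  }
  o <- stats::optim(c(log(stats::var(values)), log(maxd / 2)), obj,
                    method = "Nelder-Mead")
  structure(
    list(model = model, nugget = nugget, psill = exp(o$par[1]),
         range = exp(o$par[2]), empirical = emp),
    class = "variogram_fit"
  )
}

variogram_value <- function(psill, range, nugget, model, h) {
  s <- switch(model,
    spherical = ifelse(h < range, 1.5 * h / range - 0.5 * (h / range)^3, 1),
    exponential = 1 - exp(-h / range),
    gaussian = 1 - exp(-(h / range)^2)
  )
  out <- nugget + psill * s
  out[h == 0] <- 0 # gamma(0) = 0: the nugget acts only at h > 0
  out
}

#' Ordinary kriging of a trait over a grid
#'
#' Solves the ordinary-kriging system (semivariogram form, unbiasedness
#' constraint) once and predicts at every grid node. With a zero nugget the
#' predictor interpolates the data exactly.
#'
#' @param points two-column coordinate matrix (>= 3 non-collinear rows).
#' @param values observations at `points`.
#' @param grid a [grid_spec()].
#' @param variogram a [fit_variogram()] result (fitted automatically when
#'   `NULL`).
#' @param trait_name label stored on the surface.
#' @return An object of class `performance_surface`: `grid`, `values`
#'   (`n_x` x `n_y` matrix), `trait_name`, `variogram`, plus the data needed
#'   to predict at new locations with [krige_predict()].
#' @export
krige_surface <- function(points, values, grid, variogram = NULL,
                          trait_name = "trait") {
  pts <- score_xy(points)
  if (nrow(pts) < 3) stop("need >= 3 points")
  if (is.null(variogram)) variogram <- fit_variogram(pts, values)
  dup <- as.matrix(stats::dist(pts))
  diag(dup) <- Inf
  if (any(dup < 1e-12)) {
    warning("duplicate points jittered by 1e-8 to keep the kriging system regular")
    jit <- 1e-8 * max(diff(range(pts[, 1])), diff(range(pts[, 2])))
    dup_idx <- which(apply(dup < 1e-12, 1, any))
    pts[dup_idx, ] <- pts[dup_idx, ] + jit * seq_along(dup_idx)
  }
  n <- nrow(pts)
  G <- variogram_gamma(variogram, as.matrix(stats::dist(pts)))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  # tiny ridge keeps a flat (zero-sill) variogram solvable; prediction then
  # degrades gracefully to the sample mean
  if (variogram$psill <= 1e-12) diag(A)[seq_len(n)] <- diag(A)[seq_len(n)] + 1e-8
  nodes <- as.matrix(expand.grid(x = grid$x, y = grid$y))
  pred <- krige_solve(A, pts, values, nodes, variogram)
  structure(
    list(grid = grid, values = matrix(pred, grid$n_x, grid$n_y),
         trait_name = trait_name, variogram = variogram,
         points = pts, obs = values, A = A),
    class = "performance_surface"
  )
}

variogram_gamma <- function(v, d) {
  matrix(variogram_value(v$psill, v$range, v$nugget, v$model, d), nrow(d), ncol(d))
}

krige_solve <- function(A, pts, values, nodes, variogram) {
  n <- nrow(pts)
  d0 <- sqrt(outer(pts[, 1], nodes[, 1], "-")^2 + outer(pts[, 2], nodes[, 2], "-")^2)
  B <- rbind(variogram_gamma(variogram, d0), 1)
  lam <- solve(A, B)
  as.vector(crossprod(lam[seq_len(n), , drop = FALSE], values))
}

#' Predict a kriged surface at new locations
#'
#' Exact ordinary-kriging prediction (not grid interpolation) from the stored
#' system of a [krige_surface()] fit.
#'
#' @param surface a `performance_surface`.
#' @param newpoints two-column coordinate matrix.
#' @return Numeric vector of predictions.
#' @export
krige_predict <- function(surface, newpoints) {
  krige_solve(surface$A, surface$points, surface$obs,
              score_xy(newpoints), surface$variogram)
}

#' Kriged performance surfaces for all traits
#'
#' @param trait_table a [build_trait_table()] result.
#' @param morphospace a `morphospace` (or two-column score matrix whose rows
#'   follow the trait table's specimen order).
#' @param grid optional [grid_spec()]; defaults to a 100 x 100 grid padded 5%.
#' @param ... passed to [fit_variogram()].
#' @return Named list of `performance_surface`, one per trait.
#' @export
trait_surfaces <- function(trait_table, morphospace, grid = NULL, ...) {
  xy <- score_xy(morphospace)
  ids <- if (inherits(morphospace, "morphospace")) morphospace$scores$specimen else rownames(xy)
  if (is.null(grid)) grid <- grid_spec(xy)
  wide <- trait_matrix(trait_table, "scaled")
  if (!is.null(ids)) {
    wide <- wide[match(ids, wide$specimen), ]
    if (anyNA(wide$specimen)) stop("trait table and morphospace specimens differ")
  }
  traits <- setdiff(names(wide), "specimen")
  out <- lapply(traits, function(tr) {
    v <- wide[[tr]]
    vg <- fit_variogram(xy, v, ...)
    krige_surface(xy, v, grid, vg, trait_name = tr)
  })
  stats::setNames(out, traits)
}

#' Bilinear interpolation of a gridded field
#'
#' @param grid a [grid_spec()].
#' @param values `n_x` x `n_y` matrix of node values.
#' @param points two-column coordinate matrix; all points must lie inside the
#'   grid.
#' @param labels optional point labels used in error messages.
#' @return Numeric vector.
#' @export
interp_bilinear <- function(grid, values, points, labels = NULL) {
  pts <- score_xy(points)
  out_of <- pts[, 1] < grid$x_range[1] | pts[, 1] > grid$x_range[2] |
    pts[, 2] < grid$y_range[1] | pts[, 2] > grid$y_range[2]
  if (any(out_of)) {
    who <- if (!is.null(labels)) paste(labels[out_of], collapse = ", ") else
      paste(which(out_of), collapse = ", ")
    stop("points outside the grid: ", who)
  }
  ix <- pmin(pmax(findInterval(pts[, 1], grid$x), 1L), grid$n_x - 1L)
  iy <- pmin(pmax(findInterval(pts[, 2], grid$y), 1L), grid$n_y - 1L)
  tx <- (pts[, 1] - grid$x[ix]) / (grid$x[ix + 1] - grid$x[ix])
  ty <- (pts[, 2] - grid$y[iy]) / (grid$y[iy + 1] - grid$y[iy])
  v00 <- values[cbind(ix, iy)]
  v10 <- values[cbind(ix + 1L, iy)]
  v01 <- values[cbind(ix, iy + 1L)]
  v11 <- values[cbind(ix + 1L, iy + 1L)]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

#' Export a gridded field as CSV plus JSON sidecar
#'
#' @param obj a `performance_surface`, `adaptive_landscape`,
#'   `transitional_landscape` or `pareto_landscape`.
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(obj, path) {
  grid <- obj$grid
  df <- expand.grid(x = grid$x, y = grid$y)
  vals <- if (!is.null(obj$values)) obj$values else obj$score
  df$value <- as.vector(vals)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(
    n_x = grid$n_x, n_y = grid$n_y,
    x_range = grid$x_range, y_range = grid$y_range,
    class = class(obj)[1]
  )
  if (!is.null(obj$variogram)) {
    side$variogram <- obj$variogram[c("model", "nugget", "psill", "range")]
  }
  if (!is.null(obj$weights)) side$weights <- as.list(obj$weights)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
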