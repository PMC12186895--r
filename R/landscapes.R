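#' Enumerate trait-weight combinations on the unit simplex
#'
#' All non-negative weight vectors whose entries are multiples of `increment`
#' and sum to 1 — the compositions of `m = 1/increment` among `n_traits`
#' slots. For seven traits at increment 0.05 this gives
#' `choose(26, 6) = 230230` combinations.
#'
#' @param n_traits number of traits (columns).
#' @param increment weight step; `1/increment` must be an integer.
#' @return Numeric matrix, one weight vector per row (rows sum to 1), with
#'   attribute `increment`. Row order is the deterministic enumeration order
#'   used for tie-breaking downstream.
#' @export
enumerate_weights <- function(n_traits = 7, increment = 0.05) {
  m <- round(1 / increment)
  if (abs(m * increment - 1) > 1e-9) stop("1/increment must be an integer")
  W <- matrix(0L, 1, 0)
  rem <- m
  for (j in seq_len(n_traits - 1)) {
    rem_now <- if (ncol(W)) m - rowSums(W) else rep(m, nrow(W))
    reps <- rem_now + 1L
    W <- W[rep(seq_len(nrow(W)), reps), , drop = FALSE]
    W <- cbind(W, sequence(reps) - 1L)
  }
  W <- cbind(W, m - rowSums(W))
  out <- W * increment
  dimnames(out) <- NULL
  attr(out, "increment") <- increment
  out
}

surface_values_at <- function(surfaces, point) {
  pt <- matrix(as.numeric(point), 1, 2)
  vapply(surfaces, function(s) interp_bilinear(s$grid, s$values, pt), 0)
}

#' Evaluate a weighted landscape at a point
#'
#' Dot product of a weight vector with the surfaces' bilinearly interpolated
#' values at `point`.
#'
#' @param surfaces named list of `performance_surface` on one shared grid.
#' @param weights numeric weight vector (same length/order as `surfaces`).
#' @param point length-2 morphospace coordinate inside the grid.
#' @return Numeric scalar.
#' @export
landscape_at <- function(surfaces, weights, point) {
  sum(weights * surface_values_at(surfaces, point))
}

new_adaptive_landscape <- function(grid, values, weights, focal, top_fraction,
                                   n_combos) {
  structure(
    list(grid = grid, values = values, weights = weights, focal = focal,
         top_fraction = top_fraction, n_combos = n_combos),
    class = "adaptive_landscape"
  )
}

#' @export
print.adaptive_landscape <- function(x, ...) {
  cat(sprintf("<adaptive_landscape: %dx%d grid, focal %s>\n",
              x$grid$n_x, x$grid$n_y,
              paste(signif(unlist(x$focal), 4), collapse = ", ")))
  print(round(x$weights, 4))
  invisible(x)
}

#' Optimize an adaptive landscape for a focal point
#'
#' Scores every candidate weight vector by the height it gives the focal
#' morphospace position, averages the top `top_fraction` of vectors
#' (ties at the cutoff broken by enumeration order), renormalises the mean
#' weights to sum to 1, and returns the full-grid weighted-sum landscape
#' built from them.
#'
#' @param surfaces named list of the seven `performance_surface`s (any number
#'   works; weights columns must match).
#' @param focal_point length-2 coordinate inside the grid.
#' @param weights candidate weight matrix from [enumerate_weights()]
#'   (built automatically when `NULL`).
#' @param top_fraction fraction of best combinations averaged (default 0.10).
#' @return An `adaptive_landscape`: `grid`, `values`, the averaged `weights`
#'   (named by trait), `focal`, `top_fraction`, `n_combos`.
#' @export
optimize_landscape <- function(surfaces, focal_point, weights = NULL,
                               top_fraction = 0.10) {
  if (is.null(weights)) weights <- enumerate_weights(length(surfaces))
  if (ncol(weights) != length(surfaces)) stop("weight columns must match surfaces")
  s <- surface_values_at(surfaces, focal_point)
  heights <- as.vector(weights %*% s)
  n_top <- ceiling(top_fraction * nrow(weights))
  top <- order(heights, decreasing = TRUE)[seq_len(n_top)]
  w <- colMeans(weights[top, , drop = FALSE])
  w <- w / sum(w)
  names(w) <- names(surfaces)
  vals <- Reduce(`+`, Map(function(srf, wk) wk * srf$values, surfaces, w))
  new_adaptive_landscape(surfaces[[1]]$grid, vals, w,
                         focal = as.numeric(focal_point),
                         top_fraction = top_fraction, n_combos = nrow(weights))
}

#' Adaptive landscape for a group of specimens
#'
#' `mode = "mean_point"` (default) optimises the height of the group's mean
#' morphospace position; `mode = "mean_height"` optimises the mean height of
#' all member positions.
#'
#' @param surfaces named list of `performance_surface`s.
#' @param scores two-column coordinates of the group's members (matrix or
#'   data frame; a `morphospace` plus `group` filter also works via
#'   [score_xy()]).
#' @param weights candidate weight matrix (default full enumeration).
#' @param top_fraction fraction of best combinations averaged.
#' @param mode focal mode, see above.
#' @return An `adaptive_landscape`.
#' @export
group_landscape <- function(surfaces, scores, weights = NULL,
                            top_fraction = 0.10,
                            mode = c("mean_point", "mean_height")) {
  mode <- match.arg(mode)
  xy <- score_xy(scores)
  if (!nrow(xy)) stop("empty group")
  if (mode == "mean_point") {
    return(optimize_landscape(surfaces, colMeans(xy), weights, top_fraction))
  }
  if (is.null(weights)) weights <- enumerate_weights(length(surfaces))
  S <- vapply(seq_len(nrow(xy)), function(i) surface_values_at(surfaces, xy[i, ]),
              numeric(length(surfaces)))
  s_mean <- rowMeans(S)
  heights <- as.vector(weights %*% s_mean)
  n_top <- ceiling(top_fraction * nrow(weights))
  top <- order(heights, decreasing = TRUE)[seq_len(n_top)]
  w <- colMeans(weights[top, , drop = FALSE])
  w <- w / sum(w)
  names(w) <- names(surfaces)
  vals <- Reduce(`+`, Map(function(srf, wk) wk * srf$values, surfaces, w))
  new_adaptive_landscape(surfaces[[1]]$grid, vals, w, focal = colMeans(xy),
                         top_fraction = top_fraction, n_combos = nrow(weights))
}

#' Adaptive landscapes at reconstructed ancestral nodes
#'
#' Maximum-likelihood ancestral states under Brownian motion, per morphospace
#' axis, give each internal node a position; a landscape is then optimised at
#' each.
#'
#' @param tree a `phylo` whose tips match the score table's specimens.
#' @param scores a `morphospace` or tibble with columns `specimen`, `axis1`,
#'   `axis2`.
#' @param surfaces named list of `performance_surface`s.
#' @param weights candidate weight matrix (default full enumeration).
#' @param nodes internal-node numbers to reconstruct (default: all).
#' @param top_fraction fraction of best combinations averaged.
#' @return Named list: per node, a list with `position` and `landscape`.
#' @export
node_landscapes <- function(tree, scores, surfaces, weights = NULL,
                            nodes = NULL, top_fraction = 0.10) {
  tb <- if (inherits(scores, "morphospace")) scores$scores else scores
  a1 <- setNames(tb$axis1, tb$specimen)
  a2 <- setNames(tb$axis2, tb$specimen)
  s1 <- asr_bm(tree, a1)
  s2 <- asr_bm(tree, a2)
  if (is.null(nodes)) nodes <- as.integer(names(s1))
  if (is.null(weights)) weights <- enumerate_weights(length(surfaces))
  out <- lapply(nodes, function(nd) {
    pos <- c(s1[as.character(nd)], s2[as.character(nd)])
    list(position = unname(pos),
         landscape = optimize_landscape(surfaces, pos, weights, top_fraction))
  })
  stats::setNames(out, as.character(nodes))
}
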