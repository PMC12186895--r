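#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid — the standard geometric-morphometric size measure.
#'
#' @param landmarks a `landmark_set` tibble (columns x, y, z) or a k x d
#'   matrix.
#' @return Non-negative numeric scalar (0 flags a degenerate configuration).
#' @export
centroid_size <- function(landmarks) {
  m <- landmark_coords(landmarks)
  if (nrow(m) < 2) stop("need >= 2 landmarks")
  ctr <- colMeans(m)
  sqrt(sum(sweep(m, 2, ctr)^2))
}

landmark_coords <- function(landmarks) {
  if (is.matrix(landmarks)) return(landmarks)
  if (is.data.frame(landmarks)) {
    cols <- intersect(c("x", "y", "z"), names(landmarks))
    return(as.matrix(landmarks[, cols, drop = FALSE]))
  }
  stop("landmarks must be a matrix or a landmark-set data frame")
}

# rotation-only orthogonal Procrustes of X onto Y (both centered)
kabsch <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes alignment
#'
#' Translates each configuration to the origin, scales to unit centroid size,
#' and iteratively rotates all configurations onto the evolving mean shape
#' (rotation only, no reflection) until the mean stabilises.
#'
#' @param landmark_sets a list of landmark matrices / `landmark_set` tibbles
#'   (identical landmark counts), or one tibble holding several specimens in a
#'   `specimen` column.
#' @param tol convergence tolerance on the mean-shape change.
#' @param max_iter iteration cap.
#' @return An object of class `procrustes_result`: `aligned` (k x 3 x n
#'   array), `centroid_sizes` (named), `mean_shape`, `specimens`.
#' @export
gpa <- function(landmark_sets, tol = 1e-10, max_iter = 200) {
  if (is.data.frame(landmark_sets)) {
    landmark_sets <- split(landmark_sets, landmark_sets$specimen)[
      unique(landmark_sets$specimen)
    ]
  }
  n <- length(landmark_sets)
  if (n < 2) stop("need >= 2 landmark sets")
  mats <- lapply(landmark_sets, landmark_coords)
  k <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 0L) != k)) stop("landmark counts differ across specimens")
  ids <- names(landmark_sets) %||% sprintf("specimen_%02d", seq_len(n))
  cs <- vapply(mats, centroid_size, 0)
  scaled <- lapply(seq_len(n), function(i) {
    m <- mats[[i]]
    m <- sweep(m, 2, colMeans(m))
    m / cs[i]
  })
  ref <- scaled[[1]]
  for (it in seq_len(max_iter)) {
    rotated <- lapply(scaled, function(m) m %*% kabsch(m, ref))
    mean_shape <- Reduce(`+`, rotated) / n
    mean_shape <- mean_shape / sqrt(sum(sweep(mean_shape, 2, colMeans(mean_shape))^2))
    delta <- sqrt(sum((mean_shape - ref)^2))
    ref <- mean_shape
    if (delta < tol) break
  }
  aligned <- array(unlist(rotated), dim = c(k, ncol(ref), n),
                   dimnames = list(NULL, NULL, ids))
  structure(
    list(aligned = aligned, centroid_sizes = setNames(cs, ids),
         mean_shape = ref, specimens = ids, iterations = it),
    class = "procrustes_result"
  )
}

flatten_shapes <- function(proc) {
  X <- t(apply(proc$aligned, 3, as.vector))
  rownames(X) <- proc$specimens
  X
}

new_morphospace <- function(scores, axes, var_explained, method, groups) {
  structure(
    list(
      scores = tibble::tibble(
        specimen = rownames(scores),
        axis1 = scores[, 1],
        axis2 = if (ncol(scores) >= 2) scores[, 2] else rep(0, nrow(scores)),
        group = groups
      ),
      all_scores = scores,
      axes = axes,
      var_explained = var_explained,
      method = method
    ),
    class = "morphospace"
  )
}

#' Principal components of Procrustes-aligned shapes
#'
#' @param proc a [gpa()] result.
#' @param n_axes number of axes to retain (default all non-trivial).
#' @return An object of class `morphospace` with `scores` tibble (axis1,
#'   axis2), full score matrix, loading `axes` and per-axis
#'   `var_explained`.
#' @export
pca_shapes <- function(proc, n_axes = NULL) {
  X <- flatten_shapes(proc)
  if (nrow(X) < 3) stop("need >= 3 specimens for PCA")
  Xc <- sweep(X, 2, colMeans(X))
  s <- svd(Xc)
  keep <- min(n_axes %||% (nrow(X) - 1), sum(s$d > 1e-12 * s$d[1]))
  scores <- s$u[, seq_len(keep), drop = FALSE] %*% diag(s$d[seq_len(keep)], keep)
  rownames(scores) <- proc$specimens
  ve <- s$d^2 / sum(s$d^2)
  new_morphospace(scores, s$v[, seq_len(keep), drop = FALSE], ve[seq_len(keep)],
                  "pca", groups = rep(NA_character_, nrow(X)))
}

#' Between-groups principal components
#'
#' PCA of the group-mean matrix (groups equally weighted, centred on the grand
#' mean of group means); every specimen is projected onto the resulting axes.
#' With g groups there are at most g - 1 axes.
#'
#' @param proc a [gpa()] result.
#' @param groups per-specimen labels (>= 2 distinct).
#' @return A `morphospace` (method `"bgpca"`); `var_explained` is the fraction
#'   of between-group variance per axis.
#' @export
bgpca <- function(proc, groups) {
  X <- flatten_shapes(proc)
  groups <- as.character(groups)
  if (length(groups) != nrow(X)) stop("groups must match specimens")
  gl <- unique(groups)
  if (length(gl) < 2) stop("need >= 2 groups for bgPCA")
  M <- do.call(rbind, lapply(gl, function(g) colMeans(X[groups == g, , drop = FALSE])))
  grand <- colMeans(M)
  Mc <- sweep(M, 2, grand)
  s <- svd(Mc)
  keep <- min(length(gl) - 1, sum(s$d > 1e-10 * max(s$d, 1e-300)))
  if (keep == 0) stop("groups have identical means: no between-group variance")
  axes <- s$v[, seq_len(keep), drop = FALSE]
  scores <- sweep(X, 2, grand) %*% axes
  rownames(scores) <- proc$specimens
  ve <- (s$d^2 / sum(s$d^2))[seq_len(keep)]
  new_morphospace(scores, axes, ve, "bgpca", groups)
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("<morphospace (%s): %d specimens, %d axes; var explained %s>\n",
              x$method, nrow(x$scores), ncol(x$all_scores),
              paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", ")))
  invisible(x)
}

#' Permutation test for group separation in morphospace
#'
#' Statistic: between-group sum of squares as a fraction of the total sum of
#' squares of the scores. The p-value is `(1 + #{permuted >= observed}) /
#' (n_perm + 1)`.
#'
#' @param scores numeric matrix (or the `scores` tibble of a `morphospace`).
#' @param groups per-specimen labels.
#' @param n_perm number of label permutations (>= 99).
#' @param seed RNG seed.
#' @return A list: `statistic` (R^2), `p_value`, `n_perm`.
#' @export
permutation_group_test <- function(scores, groups, n_perm = 999, seed = 1L) {
  if (is.data.frame(scores)) {
    scores <- as.matrix(scores[, vapply(scores, is.numeric, TRUE), drop = FALSE])
  }
  if (n_perm < 99) stop("n_perm must be >= 99")
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  r2 <- function(g) {
    ctr <- colMeans(scores)
    sst <- sum(sweep(scores, 2, ctr)^2)
    ssb <- sum(vapply(unique(g), function(gl) {
      idx <- g == gl
      sum(idx) * sum((colMeans(scores[idx, , drop = FALSE]) - ctr)^2)
    }, 0))
    ssb / sst
  }
  obs <- r2(groups)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) r2(sample(groups)), 0)
  list(statistic = obs, p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}
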