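#' @importFrom stats optim optimize setNames var
NULL

# Depth (time from root) of every node; root = 0.
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  depth <- numeric(n + m)
  edge <- tree$edge
  # preorder: parents before children
  ord <- rev(postorder_edges(tree))
  for (e in ord) depth[edge[e, 2]] <- depth[edge[e, 1]] + tree$edge.length[e]
  depth
}

# Edge indices in postorder (children before parents).
postorder_edges <- function(tree) {
  tp <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  tp
}

# Per-node accumulated OU regime weights in Y-space:
# g_r(node) = sum over root-path segments painted r of exp(a*t_end)-exp(a*t_start).
# Rows ordered 1..(ntip+nnode); only tip rows are typically used.
ou_regime_weights <- function(tree, painting, alpha) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  regimes <- unique(c(painting$root_regime, painting$edge_regimes))
  depth <- node_depths(tree)
  G <- matrix(0, n + m, length(regimes), dimnames = list(NULL, regimes))
  edge <- tree$edge
  ord <- rev(postorder_edges(tree))
  for (e in ord) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    G[ch, ] <- G[p, ]
    r <- painting$edge_regimes[e]
    G[ch, r] <- G[ch, r] + exp(alpha * depth[ch]) - exp(alpha * depth[p])
  }
  G[seq_len(n), , drop = FALSE]
}

# Felsenstein pruning for a Gaussian tree model: centered tip values xc (in
# tip-label order), branch-length vector el (one per edge). Returns the
# structure log-determinant and the quadratic form, so that
# loglik(sigma2) = -0.5 * (n*log(2*pi*sigma2) + logdet + ss/sigma2).
prune_gauss <- function(tree, el, xc) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  edge <- tree$edge
  post <- postorder_edges(tree)
  mu <- numeric(n + m)
  vv <- numeric(n + m)
  mu[seq_len(n)] <- xc
  seen <- logical(n + m) # has a node's folded value been started?
  seen[seq_len(n)] <- TRUE
  logdet <- 0
  ss <- 0
  for (e in post) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    Vc <- vv[ch] + el[e]
    if (!seen[p]) {
      mu[p] <- mu[ch]
      vv[p] <- Vc
      seen[p] <- TRUE
    } else {
      V1 <- vv[p]; V2 <- Vc
      logdet <- logdet + log(V1 + V2)
      ss <- ss + (mu[p] - mu[ch])^2 / (V1 + V2)
      mu[p] <- (V2 * mu[p] + V1 * mu[ch]) / (V1 + V2)
      vv[p] <- V1 * V2 / (V1 + V2)
    }
  }
  root <- n + 1L
  logdet <- logdet + log(vv[root])
  ss <- ss + mu[root]^2 / vv[root]
  list(logdet = logdet, ss = ss, n = n)
}

check_tip_values <- function(tree, x) {
  if (is.null(names(x))) {
    if (length(x) != length(tree$tip.label)) stop("tip values do not match tree tips")
    names(x) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stop("missing tip values for: ", paste(miss, collapse = ", "))
  x[tree$tip.label]
}

#' Brownian-motion log-likelihood on a tree
#'
#' `bm_loglik()` evaluates the multivariate-normal log density of tip values
#' under single-rate Brownian motion with root state `x0`;
#' `bm_trend_loglik()` adds a directional trend so the expected tip value is
#' `x0 + trend * depth`. Two routes are available: the linear-time pruning
#' recursion and a dense GLS evaluation built on the phylogenetic covariance
#' matrix — they agree to numerical precision and serve as mutual checks.
#'
#' @param tree a `phylo` object.
#' @param x named numeric vector of tip values.
#' @param sigma2 Brownian rate (> 0).
#' @param x0 root state.
#' @param method `"pruning"` or `"dense"`.
#' @return Log-likelihood (numeric scalar).
#' @export
bm_loglik <- function(tree, x, sigma2, x0, method = c("pruning", "dense")) {
  method <- match.arg(method)
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  x <- check_tip_values(tree, x)
  xc <- x - x0
  if (method == "pruning") {
    pr <- prune_gauss(tree, tree$edge.length, xc)
    -0.5 * (pr$n * log(2 * pi * sigma2) + pr$logdet + pr$ss / sigma2)
  } else {
    dense_gauss_loglik(ape::vcv(tree) * sigma2, xc)
  }
}

#' @rdname bm_loglik
#' @param trend per-unit-time drift in the expected value.
#' @export
bm_trend_loglik <- function(tree, x, sigma2, trend, x0,
                            method = c("pruning", "dense")) {
  method <- match.arg(method)
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  x <- check_tip_values(tree, x)
  Td <- node_depths(tree)[seq_along(tree$tip.label)]
  xc <- x - x0 - trend * Td
  if (method == "pruning") {
    pr <- prune_gauss(tree, tree$edge.length, xc)
    -0.5 * (pr$n * log(2 * pi * sigma2) + pr$logdet + pr$ss / sigma2)
  } else {
    dense_gauss_loglik(ape::vcv(tree) * sigma2, xc)
  }
}

dense_gauss_loglik <- function(V, xc) {
  U <- chol(V)
  z <- backsolve(U, xc, transpose = TRUE)
  -0.5 * (length(xc) * log(2 * pi) + 2 * sum(log(diag(U))) + sum(z^2))
}

#' Ornstein-Uhlenbeck log-likelihood with regimes
#'
#' Hansen-model log density of tip values under an OU process with attraction
#' strength `alpha`, diffusion `sigma2`, per-regime optima `theta`, and a
#' branch regime painting. The pruning route exploits the fact that scaling
#' each tip by `exp(alpha * depth)` turns the OU covariance into a
#' tree-additive (BM-like) covariance with exponentially transformed branch
#' lengths; the dense route evaluates the covariance matrix directly.
#'
#' @inheritParams bm_loglik
#' @param alpha attraction strength (> 0).
#' @param theta named vector of regime optima.
#' @param painting a [paint_all()]/[paint_clade()] regime painting covering
#'   every branch.
#' @param x0 root state; `NULL` pins it to the root regime's optimum.
#' @export
ou_loglik <- function(tree, x, alpha, sigma2, theta, painting = NULL,
                      x0 = NULL, method = c("pruning", "dense")) {
  method <- match.arg(method)
  if (alpha <= 0) stop("alpha must be > 0")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  x <- check_tip_values(tree, x)
  if (is.null(painting)) painting <- paint_all(tree, names(theta)[1] %||% "base")
  if (length(painting$edge_regimes) != nrow(tree$edge)) stop("painting does not cover all branches")
  if (!all(painting$edge_regimes %in% names(theta))) {
    stop("theta missing for regimes: ",
         paste(setdiff(painting$edge_regimes, names(theta)), collapse = ", "))
  }
  if (is.null(x0)) x0 <- unname(theta[painting$root_regime])
  ntip <- length(tree$tip.label)
  Td <- node_depths(tree)[seq_len(ntip)]
  if (method == "dense") {
    mc <- model_mean_cov(tree, list(model = "OU", alpha = alpha, sigma2 = sigma2,
                                    theta = theta, painting = painting, x0 = x0))
    return(dense_gauss_loglik(mc$cov, x - mc$mean))
  }
  # Y-space: y_i = x_i * exp(alpha*T_i); Cov(Y) = sigma2 * C' with C' additive
  # along branches, branch (a,b) contributing (e^{2ab}-e^{2aa})/(2a).
  G <- ou_regime_weights(tree, painting, alpha)
  meanY <- x0 + as.vector(G[, names(theta), drop = FALSE] %*% theta)
  yc <- x * exp(alpha * Td) - meanY
  depth <- node_depths(tree)
  a2 <- 2 * alpha
  el <- (exp(a2 * depth[tree$edge[, 2]]) - exp(a2 * depth[tree$edge[, 1]])) / a2
  pr <- prune_gauss(tree, el, yc)
  ll_y <- -0.5 * (pr$n * log(2 * pi * sigma2) + pr$logdet + pr$ss / sigma2)
  ll_y + alpha * sum(Td)
}
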