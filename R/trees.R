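#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] with explicit
#' handling of missing branch lengths: `strict` mode (default) refuses trees
#' without lengths, `lenient` mode substitutes 0 with a warning.
#'
#' @param text a Newick string (or file content pasted into one string).
#' @param mode `"strict"` or `"lenient"` treatment of missing branch lengths.
#' @return `read_newick()` returns an [ape::read.tree()] `phylo` object;
#'   `write_newick()` returns a Newick string.
#' @export
read_newick <- function(text, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree found in input")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (mode == "strict") stop("tree has missing branch lengths (strict mode)")
    warning("missing branch lengths set to 0 (lenient mode)")
    if (is.null(tree$edge.length)) tree$edge.length <- numeric(nrow(tree$edge))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 15)
}

#' Simulate a birth-death phylogeny
#'
#' Wraps [ape::rphylo()] under a fixed seed. With `retain_extinct = TRUE` the
#' extinct lineages are kept as fossil tips, giving a non-ultrametric tree of
#' the kind produced by time-calibrated fossil supertrees.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth_rate,death_rate speciation and extinction rates;
#'   `birth_rate > death_rate >= 0`.
#' @param seed integer RNG seed.
#' @param retain_extinct keep extinct lineages as tips.
#' @return A `phylo` object with positive branch lengths.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, death_rate = 0, seed = 1L,
                          retain_extinct = FALSE) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (!(birth_rate > death_rate && death_rate >= 0)) {
    stop("need birth_rate > death_rate >= 0")
  }
  set.seed(seed)
  for (i in 1:25) {
    tree <- tryCatch(
      ape::rphylo(n_tips, birth = birth_rate, death = death_rate,
                  fossils = retain_extinct),
      error = function(e) NULL
    )
    if (!is.null(tree) && all(tree$edge.length >= 0)) {
      # guard against exactly-zero branches from simultaneous events
      tree$edge.length[tree$edge.length == 0] <- .Machine$double.eps
      return(tree)
    }
  }
  stop("tree simulation failed after 25 attempts")
}

#' Regime paintings on a phylogeny
#'
#' A painting assigns one regime label to every branch (edge) of the tree plus
#' a root regime. `paint_all()` paints everything one colour;
#' `paint_clade()` repaints the crown branch of `node` and every branch in its
#' subtree (later, nested repaints win because they are applied afterwards).
#'
#' @param tree a `phylo` object.
#' @param label regime label.
#' @return A list with `edge_regimes` (character, one per row of `tree$edge`)
#'   and `root_regime`.
#' @export
paint_all <- function(tree, label = "base") {
  structure(
    list(edge_regimes = rep(label, nrow(tree$edge)), root_regime = label),
    class = "regime_painting"
  )
}

#' @rdname paint_all
#' @param painting an existing painting to modify.
#' @param node the crown node (or tip index) whose stem branch and descendants
#'   are repainted.
#' @export
paint_clade <- function(painting, tree, node, label) {
  desc <- subtree_edges(tree, node)
  painting$edge_regimes[desc] <- label
  painting
}

# edge indices of the stem branch of `node` and all branches in its subtree
subtree_edges <- function(tree, node) {
  edge <- tree$edge
  stem <- which(edge[, 2] == node)
  out <- stem
  frontier <- node
  repeat {
    kids <- which(edge[, 1] %in% frontier)
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- edge[kids, 2]
  }
  sort(unique(out))
}

#' Simulate a continuous trait on a tree
#'
#' Draws tip values from the exact multivariate normal distribution implied by
#' the model: Brownian motion (`BM`), Brownian motion with a directional trend
#' (`BMtrend`), or an Ornstein-Uhlenbeck process with one or more optima
#' (`OU`) painted on branches.
#'
#' @param tree a `phylo` object.
#' @param model a list: `list(model = "BM", sigma2, x0)`,
#'   `list(model = "BMtrend", sigma2, trend, x0)`, or
#'   `list(model = "OU", alpha, sigma2, theta, painting, x0)` where `theta` is
#'   a named vector of per-regime optima, `painting` a [paint_all()] object
#'   (defaults to one regime named after `theta`), and `x0` optionally the
#'   root state (defaults to the root regime's optimum).
#' @param seed integer RNG seed.
#' @return Named numeric vector of tip values.
#' @export
evolve_trait <- function(tree, model, seed = 1L) {
  mc <- model_mean_cov(tree, model)
  set.seed(seed)
  n <- length(mc$mean)
  ch <- chol(mc$cov + diag(1e-12 * max(diag(mc$cov), 1), n))
  x <- as.vector(mc$mean + t(ch) %*% stats::rnorm(n))
  stats::setNames(x, tree$tip.label)
}

# Dense mean vector and tip covariance matrix for a trait-evolution model.
model_mean_cov <- function(tree, model) {
  n <- length(tree$tip.label)
  S <- ape::vcv(tree)
  Td <- diag(S)
  type <- model$model
  if (type == "BM") {
    if (model$sigma2 < 0) stop("sigma2 must be >= 0")
    list(mean = rep(model$x0, n), cov = model$sigma2 * S)
  } else if (type == "BMtrend") {
    if (model$sigma2 < 0) stop("sigma2 must be >= 0")
    list(mean = model$x0 + model$trend * Td, cov = model$sigma2 * S)
  } else if (type == "OU") {
    if (model$alpha < 0) stop("alpha must be >= 0")
    if (model$sigma2 <= 0) stop("sigma2 must be > 0")
    painting <- model$painting
    if (is.null(painting)) painting <- paint_all(tree, names(model$theta)[1] %||% "base")
    theta <- model$theta
    if (is.null(names(theta))) names(theta) <- painting$root_regime
    x0 <- model$x0 %||% unname(theta[painting$root_regime])
    a <- model$alpha
    G <- ou_regime_weights(tree, painting, a) # tips x regimes, Y-space
    meanY <- x0 + as.vector(G[, names(theta), drop = FALSE] %*% theta)
    mean_x <- exp(-a * Td) * meanY
    D <- outer(Td, Td, "+") - 2 * S
    V <- model$sigma2 / (2 * a) * exp(-a * D) * (1 - exp(-2 * a * S))
    list(mean = mean_x, cov = V)
  } else {
    stop("unknown model type: ", type)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
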