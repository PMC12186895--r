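#' Fit a model of continuous trait evolution by maximum likelihood
#'
#' Supported models: single-rate Brownian motion (`BM1`), Brownian motion with
#' a trend (`BMtrend`), multi-rate Brownian motion with per-regime rates
#' (`BMM`), single-peak Ornstein-Uhlenbeck (`OU1`) and multi-peak OU (`OUM`).
#' Location parameters (root state, optima, trend) are profiled out by GLS at
#' each candidate value of the shape parameters (OU `alpha`, relative BM
#' rates), which are optimized by bounded quasi-Newton from several
#' deterministic starting points; the diffusion `sigma2` has a closed-form ML
#' solution throughout. On ultrametric trees the OU root state is pinned to
#' the root regime's optimum because the corresponding design column is
#' exactly collinear; on non-ultrametric trees it is a free parameter.
#'
#' @param tree a `phylo` object.
#' @param x named numeric vector of tip values.
#' @param model one of `"BM1"`, `"BMtrend"`, `"BMM"`, `"OU1"`, `"OUM"`.
#' @param painting regime painting (required for `BMM` and `OUM`).
#' @param n_starts number of optimizer starting points.
#' @return An object of class `evo_fit`: model name, parameter estimates,
#'   log-likelihood, parameter count, AIC and AICc.
#' @export
fit_model <- function(tree, x,
                      model = c("BM1", "BMtrend", "BMM", "OU1", "OUM"),
                      painting = NULL, n_starts = 5) {
  model <- match.arg(model)
  x <- check_tip_values(tree, x)
  n <- length(x)
  Td <- node_depths(tree)[seq_len(n)]
  Th <- max(Td)
  fit <- switch(model,
    BM1 = fit_gls_bm(tree, x, D = matrix(1, n, 1, dimnames = list(NULL, "x0"))),
    BMtrend = fit_gls_bm(tree, x, D = cbind(x0 = 1, trend = Td)),
    BMM = fit_bmm(tree, x, painting, n_starts),
    OU1 = fit_ou(tree, x, paint_all(tree, "theta"), n_starts),
    OUM = fit_ou(tree, x, painting, n_starts)
  )
  k <- fit$n_params
  aic <- 2 * k - 2 * fit$loglik
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(
    list(model = model, params = fit$params, loglik = fit$loglik,
         n_params = k, AIC = aic, AICc = aicc, n = n,
         painting = fit$painting %||% painting),
    class = "evo_fit"
  )
}

#' @export
print.evo_fit <- function(x, ...) {
  cat(sprintf("<evo_fit %s: logLik = %.4f, k = %d, AIC = %.4f>\n",
              x$model, x$loglik, x$n_params, x$AIC))
  print(unlist(x$params))
  invisible(x)
}

# GLS fit under a fixed tree covariance structure C (sigma2 profiled).
gls_profile <- function(C, y, D) {
  U <- chol(C)
  A <- backsolve(U, D, transpose = TRUE)
  b <- backsolve(U, y, transpose = TRUE)
  qa <- qr(A)
  beta <- qr.coef(qa, b)
  beta[is.na(beta)] <- 0
  e <- b - A %*% beta
  n <- length(y)
  s2 <- sum(e^2) / n
  ll <- -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(U))) + n)
  list(beta = as.vector(beta), sigma2 = s2, loglik = ll, rank = qa$rank)
}

fit_gls_bm <- function(tree, x, D) {
  C <- ape::vcv(tree)
  g <- gls_profile(C, x, D)
  params <- as.list(setNames(g$beta, colnames(D)))
  params$sigma2 <- g$sigma2
  list(params = params, loglik = g$loglik, n_params = ncol(D) + 1L)
}

fit_bmm <- function(tree, x, painting, n_starts) {
  if (is.null(painting)) stop("BMM requires a regime painting")
  regimes <- sort(unique(c(painting$root_regime, painting$edge_regimes)))
  k <- length(regimes)
  if (k < 2) return(c(fit_gls_bm(tree, x, matrix(1, length(x), 1, dimnames = list(NULL, "x0"))),
                      list(painting = painting)))
  ridx <- match(painting$edge_regimes, regimes)
  obj <- function(lr) { # log relative rates of regimes 2..k (regime 1 = 1)
    rate <- c(1, exp(lr))
    t2 <- tree
    t2$edge.length <- tree$edge.length * rate[ridx]
    -gls_profile(ape::vcv(t2), x, matrix(1, length(x), 1))$loglik
  }
  best <- NULL
  starts <- start_grid(k - 1, n_starts, lo = -2, hi = 2)
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                      lower = rep(-12, k - 1), upper = rep(12, k - 1))
    if (is.null(best) || o$value < best$value) best <- o
  }
  rate <- c(1, exp(best$par))
  t2 <- tree
  t2$edge.length <- tree$edge.length * rate[ridx]
  g <- gls_profile(ape::vcv(t2), x, matrix(1, length(x), 1))
  sig <- setNames(g$sigma2 * rate, paste0("sigma2_", regimes))
  list(params = c(list(x0 = g$beta[1]), as.list(sig)),
       loglik = g$loglik, n_params = k + 1L, painting = painting)
}

# deterministic spread of optimizer starting points
start_grid <- function(d, n_starts, lo, hi) {
  pts <- seq(lo, hi, length.out = max(n_starts, 2))
  m <- matrix(rep(pts[seq_len(n_starts)], each = d), nrow = n_starts, byrow = TRUE)
  m
}

fit_ou <- function(tree, x, painting, n_starts) {
  if (is.null(painting)) stop("OUM requires a regime painting")
  n <- length(x)
  Td <- node_depths(tree)[seq_len(n)]
  Th <- max(Td)
  ultra <- ape::is.ultrametric(tree, tol = 1e-8)
  regimes <- sort(unique(c(painting$root_regime, painting$edge_regimes)))
  S <- ape::vcv(tree)
  prof <- function(alpha) ou_profile(tree, x, painting, alpha, regimes, Td, S, ultra)
  obj <- function(la) -prof(exp(la))$loglik
  lo <- log(1e-8); hi <- log(50 / Th)
  best <- NULL
  for (s in seq(lo + 0.5, hi - 0.1, length.out = n_starts)) {
    o <- stats::optim(s, obj, method = "L-BFGS-B", lower = lo, upper = hi)
    if (is.null(best) || o$value < best$value) best <- o
  }
  alpha <- exp(best$par)
  p <- prof(alpha)
  theta <- setNames(p$theta, paste0("theta_", regimes))
  params <- c(list(alpha = alpha, sigma2 = p$sigma2), as.list(theta))
  if (!ultra) params$x0 <- p$x0
  k <- 2L + length(regimes) + (!ultra)
  list(params = params, loglik = p$loglik, n_params = k, painting = painting)
}

# Profile likelihood of an OU model at fixed alpha: optima (and root state on
# non-ultrametric trees) by GLS in Y-space, sigma2 closed form.
ou_profile <- function(tree, x, painting, alpha, regimes, Td, S, ultra) {
  G <- ou_regime_weights(tree, painting, alpha)[, regimes, drop = FALSE]
  CY <- (exp(2 * alpha * S) - 1) / (2 * alpha)
  y <- x * exp(alpha * Td)
  if (ultra) {
    # x0 pinned to root optimum: its weight folds into the root regime column
    D <- G
    D[, painting$root_regime] <- D[, painting$root_regime] + 1
  } else {
    D <- cbind(x0 = 1, G)
  }
  g <- gls_profile(CY, y, D)
  ll <- g$loglik + alpha * sum(Td)
  if (ultra) {
    theta <- g$beta
    x0 <- theta[match(painting$root_regime, regimes)]
  } else {
    x0 <- g$beta[1]
    theta <- g$beta[-1]
  }
  list(loglik = ll, sigma2 = g$sigma2, theta = theta, x0 = x0)
}

#' Compare fitted evolutionary models by AIC
#'
#' @param fits a list of [fit_model()] results on the same data.
#' @return A tibble with one row per model: log-likelihood, parameter count,
#'   AIC, AICc, delta AIC relative to the best model, and Akaike weights
#'   (summing to 1).
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits to compare")
  tb <- tibble::tibble(
    model = vapply(fits, function(f) f$model, ""),
    logLik = vapply(fits, function(f) f$loglik, 0),
    n_params = vapply(fits, function(f) f$n_params, 0L),
    AIC = vapply(fits, function(f) f$AIC, 0),
    AICc = vapply(fits, function(f) f$AICc, 0)
  )
  tb$dAIC <- tb$AIC - min(tb$AIC)
  w <- exp(-tb$dAIC / 2)
  tb$weight <- w / sum(w)
  dplyr::arrange(tb, .data$dAIC)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Joint ML (equivalently GLS) reconstruction: internal-node states minimise
#' the branch-length-weighted sum of squared changes, which reduces to a
#' sparse harmonic system solved directly.
#'
#' @param tree a `phylo` object.
#' @param x named numeric vector of tip values.
#' @return Named numeric vector of states for internal nodes
#'   (names are the `phylo` node numbers).
#' @export
asr_bm <- function(tree, x) {
  x <- check_tip_values(tree, x)
  n <- length(x)
  m <- tree$Nnode
  w <- 1 / pmax(tree$edge.length, 1e-12)
  edge <- tree$edge
  A <- matrix(0, m, m)
  b <- numeric(m)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1] - n # internal index of parent
    ch <- edge[e, 2]
    A[p, p] <- A[p, p] + w[e]
    if (ch > n) {
      ci <- ch - n
      A[ci, ci] <- A[ci, ci] + w[e]
      A[p, ci] <- A[p, ci] - w[e]
      A[ci, p] <- A[ci, p] - w[e]
    } else {
      b[p] <- b[p] + w[e] * x[ch]
    }
  }
  states <- solve(A, b)
  setNames(as.vector(states), as.character(n + seq_len(m)))
}

#' Forward stepwise search for OU regime shifts
#'
#' Greedy forward phase of a shift search: starting from a single-peak OU
#' model, each branch is tried as the origin of a new regime (painting the
#' branch and its subtree); the best addition is accepted only when it
#' improves AIC by more than `delta_aic`. There is no backward or
#' convergence-merging phase.
#'
#' @param tree a `phylo` object.
#' @param x named numeric vector of tip values.
#' @param delta_aic acceptance threshold on the AIC improvement (default 4).
#' @param max_shifts cap on accepted shifts.
#' @param n_starts optimizer starts per candidate fit.
#' @return A list with `painting` (the accepted regime painting), `fit` (the
#'   final model), `shift_edges` (accepted edge indices) and `trail` (a tibble
#'   of the accepted-model sequence).
#' @export
forward_shift_search <- function(tree, x, delta_aic = 4, max_shifts = 5,
                                 n_starts = 3) {
  x <- check_tip_values(tree, x)
  painting <- paint_all(tree, "base")
  current <- fit_model(tree, x, "OU1", n_starts = n_starts)
  trail <- tibble::tibble(step = 0L, shift_edge = NA_integer_,
                          model = "OU1", AIC = current$AIC)
  shifts <- integer(0)
  # quantities reused by the fixed-alpha candidate screen
  S <- ape::vcv(tree)
  Td <- diag(S)
  ultra <- ape::is.ultrametric(tree, tol = 1e-8)
  repeat {
    if (length(shifts) >= max_shifts || !is.finite(delta_aic)) break
    cand_edges <- setdiff(seq_len(nrow(tree$edge)), shifts)
    new_lab <- paste0("shift", length(shifts) + 1L)
    alpha_now <- current$params$alpha
    # screen every candidate branch at the current attraction strength
    # (optima and sigma2 profiled by GLS), then refit the best one fully
    screen <- vapply(cand_edges, function(e) {
      p2 <- paint_clade(painting, tree, tree$edge[e, 2], new_lab)
      regs <- sort(unique(c(p2$root_regime, p2$edge_regimes)))
      pr <- tryCatch(
        ou_profile(tree, x, p2, alpha_now, regs, Td, S, ultra),
        error = function(err) list(loglik = -Inf)
      )
      pr$loglik
    }, 0)
    if (!any(is.finite(screen))) break
    best_edge <- cand_edges[which.max(screen)]
    best_paint <- paint_clade(painting, tree, tree$edge[best_edge, 2], new_lab)
    best_fit <- tryCatch(
      fit_model(tree, x, "OUM", painting = best_paint, n_starts = n_starts),
      error = function(err) NULL
    )
    if (is.null(best_fit) || (current$AIC - best_fit$AIC) <= delta_aic) break
    painting <- best_paint
    current <- best_fit
    shifts <- c(shifts, best_edge)
    trail <- dplyr::bind_rows(trail, tibble::tibble(
      step = length(shifts), shift_edge = best_edge,
      model = "OUM", AIC = current$AIC
    ))
  }
  list(painting = painting, fit = current, shift_edges = shifts, trail = trail)
}

#' Re-fit models across a set of trees
#'
#' Refits and compares a list of models on each tree of a tree set (e.g. trees
#' differing in time calibration) to obtain a distribution of model support.
#'
#' @param trees a list of `phylo` objects sharing tip labels with `x`.
#' @param x named numeric vector of tip values.
#' @param models character vector of model names for [fit_model()].
#' @param paintings named list of regime paintings; entry `NULL` (or absent)
#'   for models that need none. Paintings are edge-indexed, so all trees must
#'   share topology and edge order.
#' @return A tibble with `n_trees * n_models` rows: tree id plus the
#'   [compare_models()] columns.
#' @export
tree_set_rerun <- function(trees, x, models = c("BM1", "OU1"), paintings = NULL) {
  out <- purrr::map_dfr(seq_along(trees), function(i) {
    tree <- trees[[i]]
    miss <- setdiff(tree$tip.label, names(x))
    if (length(miss)) stop("tree ", i, " has tips without values: ",
                           paste(miss, collapse = ", "))
    fits <- lapply(models, function(mn) {
      fit_model(tree, x, mn, painting = paintings[[mn]])
    })
    cmp <- compare_models(fits)
    cmp$tree <- i
    cmp
  })
  dplyr::select(out, "tree", dplyr::everything())
}
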