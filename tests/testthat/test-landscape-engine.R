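# small analytic surface on a fixed grid for engine tests
toy_grid <- function(n = 21) {
  structure(list(x = seq(0, 1, length.out = n), y = seq(0, 1, length.out = n),
                 x_range = c(0, 1), y_range = c(0, 1), n_x = n, n_y = n),
            class = "grid_spec")
}

toy_surface <- function(f, n = 21, name = "trait") {
  g <- toy_grid(n)
  vals <- outer(g$x, g$y, f)
  structure(list(grid = g, values = vals, trait_name = name),
            class = "performance_surface")
}

toy_surfaces <- function(n = 21) {
  list(
    s1 = toy_surface(function(x, y) x, n),
    s2 = toy_surface(function(x, y) y, n),
    s3 = toy_surface(function(x, y) 1 - x, n),
    s4 = toy_surface(function(x, y) 1 - y, n),
    s5 = toy_surface(function(x, y) x * y, n),
    s6 = toy_surface(function(x, y) (1 - x) * (1 - y), n),
    s7 = toy_surface(function(x, y) 0 * x + 0.5, n)
  )
}

test_that("weight enumeration matches the closed-form composition count", {
  for (m in c(2, 4, 6, 8)) {
    for (k in c(2, 3, 4)) {
      W <- enumerate_weights(k, 1 / m)
      expect_equal(nrow(W), choose(m + k - 1, k - 1))
      expect_equal(rowSums(W), rep(1, nrow(W)), tolerance = 1e-12)
      expect_false(anyDuplicated(W) > 0)
    }
  }
  expect_equal(enumerate_weights(2, 0.5),
               rbind(c(0, 1), c(0.5, 0.5), c(1, 0)),
               ignore_attr = TRUE)
  expect_error(enumerate_weights(3, 0.3), "integer")
})

test_that("brute-force nested loops confirm the enumeration for 3 traits", {
  W <- enumerate_weights(3, 0.25)
  brute <- NULL
  for (i in 0:4) for (j in 0:4) for (k in 0:4) {
    if (i + j + k == 4) brute <- rbind(brute, c(i, j, k) / 4)
  }
  expect_equal(nrow(W), 15)
  key <- function(m) sort(apply(m, 1, paste, collapse = "|"))
  expect_identical(key(W), key(brute))
})

test_that("variogram fitting responds to the structure of the data", {
  set.seed(2)
  pts <- matrix(runif(80), 40, 2)
  expect_warning(flat <- fit_variogram(pts, rep(1, 40)), "constant")
  expect_equal(flat$psill, 0)
  trend <- fit_variogram(pts, pts[, 1] * 3)
  expect_gt(trend$psill, 0)
})

test_that("variogram range is recovered from simulated spherical fields", {
  sph_cov <- function(h, sill, rg) {
    ifelse(h < rg, sill * (1 - 1.5 * h / rg + 0.5 * (h / rg)^3), 0)
  }
  true_range <- 0.8
  ranges <- vapply(1:50, function(i) {
    set.seed(1000 + i)
    pts <- matrix(runif(120, 0, 2), 60, 2)
    d <- as.matrix(dist(pts))
    C <- sph_cov(d, 1, true_range)
    x <- as.vector(t(chol(C + diag(1e-8, 60))) %*% rnorm(60))
    fit_variogram(pts, x)$range
  }, 0)
  expect_lt(abs(median(ranges) - true_range) / true_range, 0.25)
})

test_that("ordinary kriging interpolates exactly with zero nugget", {
  set.seed(5)
  pts <- matrix(runif(60), 30, 2)
  vals <- sin(4 * pts[, 1]) + pts[, 2]^2
  vg <- fit_variogram(pts, vals)
  grid <- grid_spec(pts, n_x = 25, n_y = 25)
  srf <- krige_surface(pts, vals, grid, vg)
  expect_lt(max(abs(krige_predict(srf, pts) - vals)), 1e-6)
  expect_true(all(is.finite(srf$values)))
})

test_that("far-field kriging predictions revert to the unbiased mean", {
  pts <- rbind(c(0, 0), c(0.4, 0.1), c(0.1, 0.5))
  vals <- c(2, 6, 4)
  vg <- structure(list(model = "spherical", nugget = 0, psill = 1, range = 0.5),
                  class = "variogram_fit")
  grid <- structure(list(x = seq(-60, 60, length.out = 13),
                         y = seq(-60, 60, length.out = 13),
                         x_range = c(-60, 60), y_range = c(-60, 60),
                         n_x = 13, n_y = 13), class = "grid_spec")
  srf <- krige_surface(pts, vals, grid, vg)
  far <- krige_predict(srf, matrix(c(50, 50), 1))
  expect_lt(abs(far - mean(vals)) / mean(vals), 0.01)
})

test_that("duplicate kriging points are jittered with a warning", {
  pts <- rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1), c(0.5, 0.5))
  vals <- c(1, 1, 2, 3, 4)
  vg <- structure(list(model = "spherical", nugget = 0, psill = 1, range = 1),
                  class = "variogram_fit")
  expect_warning(srf <- krige_surface(pts, vals, toy_grid(11), vg), "jitter")
  expect_true(all(is.finite(srf$values)))
})

test_that("landscape evaluation is the weighted surface combination", {
  srf <- toy_surfaces()
  pt <- c(0.3, 0.7)
  onehot <- c(0, 1, 0, 0, 0, 0, 0)
  expect_equal(landscape_at(srf, onehot, pt), 0.7, tolerance = 1e-12)
  eqw <- rep(1 / 7, 7)
  manual <- mean(c(0.3, 0.7, 0.7, 0.3, 0.21, 0.7 * 0.3, 0.5))
  expect_equal(landscape_at(srf, eqw, pt), manual, tolerance = 1e-10)
  # at grid nodes the pointwise evaluation matches the full-grid combination
  w <- c(0.2, 0.1, 0.1, 0.15, 0.15, 0.2, 0.1)
  vals <- Reduce(`+`, Map(function(s, wk) wk * s$values, srf, w))
  g <- srf[[1]]$grid
  for (idx in list(c(3, 5), c(10, 1), c(21, 21))) {
    expect_equal(landscape_at(srf, w, c(g$x[idx[1]], g$y[idx[2]])),
                 vals[idx[1], idx[2]], tolerance = 1e-10)
  }
})

test_that("optimization favours the surface that peaks at the focal point", {
  srf <- toy_surfaces()
  W <- enumerate_weights(7, 0.25)
  # focal at (1, 0): only s1 = x and s4 = 1 - y peak there; s5, s7 lag
  land <- optimize_landscape(srf, c(1, 0), W, top_fraction = 0.001)
  expect_gt(land$weights[["s1"]] + land$weights[["s4"]], 0.9)
  # the single best vector is one-hot when one surface dominates
  land2 <- optimize_landscape(srf["s5"], c(1, 1),
                              weights = matrix(1, 1, 1), top_fraction = 1)
  expect_equal(unname(land2$weights), 1)
})

test_that("averaging the whole simplex yields uniform weights by symmetry", {
  srf <- toy_surfaces()
  W <- enumerate_weights(7, 0.2)
  land <- optimize_landscape(srf, c(0.4, 0.6), W, top_fraction = 1)
  expect_equal(unname(land$weights), rep(1 / 7, 7), tolerance = 1e-12)
})

test_that("top-fraction counts follow the ceil rule", {
  W <- enumerate_weights(7, 0.05)
  expect_equal(ceiling(0.10 * nrow(W)), 23023)
  srf <- toy_surfaces()
  land <- optimize_landscape(srf, c(0.2, 0.2), W)
  expect_equal(land$n_combos, 230230)
})

test_that("landscape values scale linearly in any one surface", {
  srf <- toy_surfaces()
  w <- rep(1 / 7, 7)
  base <- Reduce(`+`, Map(function(s, wk) wk * s$values, srf, w))
  srf2 <- srf
  srf2$s3$values <- 3 * srf2$s3$values
  scaled <- Reduce(`+`, Map(function(s, wk) wk * s$values, srf2, w))
  expect_equal(scaled - base, (3 - 1) * w[3] * srf$s3$values, tolerance = 1e-12)
})

test_that("group landscapes use the member centroid as focal point", {
  srf <- toy_surfaces()
  W <- enumerate_weights(7, 0.25)
  pts <- rbind(c(0.2, 0.4), c(0.6, 0.8))
  gl <- group_landscape(srf, pts, W)
  expect_equal(gl$focal, c(0.4, 0.6))
  single <- group_landscape(srf, pts[1, , drop = FALSE], W)
  direct <- optimize_landscape(srf, pts[1, ], W)
  expect_equal(single$values, direct$values)
  # optimized landscape is at least as high at the focal as equal weights
  eqh <- landscape_at(srf, rep(1 / 7, 7), gl$focal)
  expect_gte(landscape_at(srf, gl$weights, gl$focal), eqh - 1e-12)
})

test_that("node landscapes sit at BM ancestral-state positions", {
  srf <- toy_surfaces()
  W <- enumerate_weights(7, 0.25)
  tree <- read_newick("(A:1,B:1);")
  scores <- tibble::tibble(specimen = c("A", "B"),
                           axis1 = c(0.2, 0.6), axis2 = c(0.9, 0.1))
  nl <- node_landscapes(tree, scores, srf, W)
  expect_equal(nl[["3"]]$position, c(0.4, 0.5)) # equal branches -> midpoint
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  s2 <- tibble::tibble(specimen = c("A", "B", "C", "D"),
                       axis1 = c(0.1, 0.2, 0.3, 0.8), axis2 = rep(0.5, 4))
  nl2 <- node_landscapes(star, s2, srf, W)
  expect_equal(nl2[["5"]]$position, c(mean(s2$axis1), 0.5)) # GLS mean on a star
})

test_that("optimization is invariant to weight-list order away from ties", {
  srf <- toy_surfaces()
  W <- enumerate_weights(7, 0.25)
  focal <- c(0.15, 0.85)
  s <- vapply(srf, function(x) interp_bilinear(x$grid, x$values, matrix(focal, 1)), 0)
  h <- sort(as.vector(W %*% s), decreasing = TRUE)
  # place the cutoff strictly between two distinct heights so no tie straddles it
  n_top <- which(diff(h) < -1e-9)[10]
  frac <- n_top / nrow(W)
  set.seed(1)
  perm <- sample(nrow(W))
  a <- optimize_landscape(srf, focal, W, top_fraction = frac)
  b <- optimize_landscape(srf, focal, W[perm, ], top_fraction = frac)
  expect_equal(a$weights, b$weights, tolerance = 1e-9)
})
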