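test_that("Newick round-trips preserve topology and branch lengths", {
  tr <- read_newick("(A:1,B:1):0;")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(tr$edge.length, c(1, 1))
  big <- simulate_tree(50, seed = 13, death_rate = 0.4, retain_extinct = TRUE)
  rt <- read_newick(write_newick(big))
  expect_equal(suppressWarnings(ape::dist.topo(rt, big)), 0, ignore_attr = TRUE)
  expect_equal(sort(rt$edge.length), sort(big$edge.length), tolerance = 1e-10)
  expect_error(suppressWarnings(read_newick("((A:1,B:2")), "parse error")
  expect_error(read_newick("(A,B);", mode = "strict"), "missing branch lengths")
  expect_warning(len <- read_newick("(A,B);", mode = "lenient"), "set to 0")
  expect_equal(len$edge.length, c(0, 0))
})

test_that("BM likelihood matches the hand-computed bivariate density", {
  tr <- read_newick("(A:1,B:1);")
  expect_equal(bm_loglik(tr, c(A = 0, B = 0), sigma2 = 1, x0 = 0), -log(2 * pi))
  # trend with mu = 0 reduces exactly to BM
  x <- c(A = 0.3, B = -1.2)
  expect_equal(bm_trend_loglik(tr, x, 0.7, trend = 0, x0 = 0.1),
               bm_loglik(tr, x, 0.7, x0 = 0.1))
})

test_that("pruning and dense-GLS likelihoods agree on 50-tip trees", {
  tr <- simulate_tree(50, seed = 21, death_rate = 0.3, retain_extinct = TRUE)
  x <- evolve_trait(tr, list(model = "BM", sigma2 = 1.4, x0 = 1), seed = 2)
  expect_equal(bm_loglik(tr, x, 1.4, 1, method = "pruning"),
               bm_loglik(tr, x, 1.4, 1, method = "dense"), tolerance = 1e-8)
  p <- paint_clade(paint_all(tr, "a"), tr, length(tr$tip.label) + 10L, "b")
  th <- c(a = 0, b = 2)
  expect_equal(ou_loglik(tr, x, 0.7, 1.4, th, p, method = "pruning"),
               ou_loglik(tr, x, 0.7, 1.4, th, p, method = "dense"),
               tolerance = 1e-8)
})

test_that("OU collapses to BM in the weak-selection limit", {
  tr <- simulate_tree(40, seed = 5)
  x <- evolve_trait(tr, list(model = "BM", sigma2 = 0.9, x0 = 2), seed = 3)
  ll_ou <- ou_loglik(tr, x, alpha = 1e-8, sigma2 = 0.9, theta = c(base = 2))
  ll_bm <- bm_loglik(tr, x, 0.9, 2)
  expect_equal(ll_ou, ll_bm, tolerance = 1e-4)
})

test_that("strong-selection OU tip means sit on the optimum", {
  tr <- read_newick("(A:1,B:1);")
  mc <- 0
  for (i in 1:200) {
    mc <- mc + evolve_trait(tr, list(model = "OU", alpha = 60, sigma2 = 0.4,
                                     theta = c(base = 3)), seed = 4000 + i)
  }
  expect_lt(max(abs(mc / 200 - 3)), 0.05)
  # unpainted branches are rejected
  p <- paint_all(tr, "a")
  p$edge_regimes[1] <- "mystery"
  expect_error(ou_loglik(tr, c(A = 0, B = 0), 1, 1, c(a = 0), p), "mystery")
})

test_that("ancestral states solve the GLS harmonic system", {
  cherry <- read_newick("(A:1,B:1);")
  expect_equal(unname(asr_bm(cherry, c(A = 0, B = 4))), 2)
  uneven <- read_newick("(A:1,B:3);")
  expect_equal(unname(asr_bm(uneven, c(A = 0, B = 4))), 1) # inverse-length weights
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  x <- c(A = 1, B = 2, C = 3, D = 10)
  expect_equal(unname(asr_bm(star, x)), mean(x))
  const <- asr_bm(simulate_tree(20, seed = 8), setNames(rep(5, 20), simulate_tree(20, seed = 8)$tip.label))
  expect_true(all(abs(const - 5) < 1e-10))
  # cross-check against an independent ML implementation
  tr <- simulate_tree(25, seed = 30)
  xv <- evolve_trait(tr, list(model = "BM", sigma2 = 1, x0 = 0), seed = 6)
  ours <- asr_bm(tr, xv)
  theirs <- ape::ace(xv[tr$tip.label], tr, method = "REML")$ace
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-4)
})

test_that("ML fitting recovers generating parameters", {
  # sigma2 under BM: median within 10% over replicates on 100-tip trees
  tr <- simulate_tree(100, seed = 55)
  sig <- vapply(1:200, function(i) {
    x <- evolve_trait(tr, list(model = "BM", sigma2 = 1, x0 = 0), seed = 6000 + i)
    fit_model(tr, x, "BM1")$params$sigma2
  }, 0)
  expect_lt(abs(median(sig) - 1), 0.1)
  # OUM optima with well-separated regimes
  tr2 <- simulate_tree(60, seed = 17)
  Th <- max(ape::node.depth.edgelength(tr2))
  p <- paint_clade(paint_all(tr2, "a"), tr2, 62L + 15L, "b")
  alpha <- 10 / Th
  theta_err <- vapply(1:40, function(i) {
    x <- evolve_trait(tr2, list(model = "OU", alpha = alpha, sigma2 = 0.5,
                                theta = c(a = 0, b = 5), painting = p),
                      seed = 7000 + i)
    f <- fit_model(tr2, x, "OUM", painting = p)
    max(abs(f$params$theta_a - 0), abs(f$params$theta_b - 5))
  }, 0)
  expect_lt(median(theta_err), 0.5)
})

test_that("OU1 log-likelihood dominates BM1 (boundary nesting)", {
  tr <- simulate_tree(40, seed = 3)
  for (i in 1:5) {
    x <- evolve_trait(tr, list(model = "BM", sigma2 = 1, x0 = 0), seed = 80 + i)
    expect_gte(fit_model(tr, x, "OU1")$loglik,
               fit_model(tr, x, "BM1")$loglik - 1e-6)
  }
})

test_that("multi-rate BM detects strongly unequal rates", {
  tr <- simulate_tree(60, seed = 71)
  p <- paint_clade(paint_all(tr, "slow"), tr, 62L + 20L, "fast")
  regimes <- p$edge_regimes
  t2 <- tr
  t2$edge.length <- tr$edge.length * ifelse(regimes == "fast", 25, 1)
  x <- evolve_trait(t2, list(model = "BM", sigma2 = 0.4, x0 = 0), seed = 9)
  names(x) <- tr$tip.label
  f1 <- fit_model(tr, x, "BM1")
  fm <- fit_model(tr, x, "BMM", painting = p)
  expect_gt(f1$AIC - fm$AIC, 4)
  expect_gt(fm$params$sigma2_fast / fm$params$sigma2_slow, 5)
})

test_that("model comparison computes delta-AIC and Akaike weights", {
  f1 <- structure(list(model = "A", loglik = -10, n_params = 2L,
                       AIC = 24, AICc = 24.5, n = 20), class = "evo_fit")
  f2 <- structure(list(model = "B", loglik = -10, n_params = 2L,
                       AIC = 24, AICc = 24.5, n = 20), class = "evo_fit")
  cmp <- compare_models(list(f1, f2))
  expect_equal(cmp$weight, c(0.5, 0.5))
  f3 <- structure(list(model = "C", loglik = -11, n_params = 2L,
                       AIC = 26, AICc = 26.5, n = 20), class = "evo_fit")
  cmp2 <- compare_models(list(f1, f3))
  expect_equal(cmp2$weight[2] / cmp2$weight[1], exp(-1))
  expect_equal(cmp2$dAIC, c(0, 2))
})

test_that("the generating model wins the AIC comparison under strong signal", {
  tr <- simulate_tree(80, seed = 41)
  Th <- max(ape::node.depth.edgelength(tr))
  wins <- vapply(1:30, function(i) {
    x <- evolve_trait(tr, list(model = "OU", alpha = 15 / Th, sigma2 = 1,
                               theta = c(base = 0)), seed = 8500 + i)
    fits <- list(fit_model(tr, x, "BM1"), fit_model(tr, x, "OU1"))
    compare_models(fits)$model[1] == "OU1"
  }, TRUE)
  expect_gte(mean(wins), 0.8)
})

test_that("tidy and glance summarise fitted models", {
  tr <- simulate_tree(20, seed = 2)
  x <- evolve_trait(tr, list(model = "BM", sigma2 = 1, x0 = 0), seed = 1)
  f <- fit_model(tr, x, "BM1")
  td <- tidy(f)
  expect_setequal(td$term, c("x0", "sigma2"))
  gl <- glance(f)
  expect_equal(gl$AIC, f$AIC)
  expect_equal(gl$n_tips, 20L)
})

test_that("forward search returns OU1 under an infinite threshold", {
  tr <- simulate_tree(20, seed = 19)
  x <- evolve_trait(tr, list(model = "BM", sigma2 = 1, x0 = 0), seed = 4)
  out <- forward_shift_search(tr, x, delta_aic = Inf)
  expect_length(out$shift_edges, 0)
  expect_equal(out$fit$model, "OU1")
  expect_equal(nrow(out$trail), 1)
})

test_that("tree-set reruns tabulate support across trees", {
  tr <- simulate_tree(20, seed = 23)
  x <- evolve_trait(tr, list(model = "BM", sigma2 = 1, x0 = 0), seed = 2)
  same <- tree_set_rerun(rep(list(tr), 5), x, models = c("BM1", "OU1"))
  expect_equal(nrow(same), 10) # n_trees x n_models
  spread <- tapply(same$weight, same$model, stats::sd)
  expect_true(all(spread == 0)) # identical trees -> zero variance
  # jittered branch lengths under strong OU signal keep OU1 preferred
  Th <- max(ape::node.depth.edgelength(tr))
  xo <- evolve_trait(tr, list(model = "OU", alpha = 20 / Th, sigma2 = 1,
                              theta = c(base = 0)), seed = 3)
  trees <- lapply(1:10, function(i) {
    set.seed(900 + i)
    t2 <- tr
    t2$edge.length <- tr$edge.length * runif(nrow(tr$edge), 0.9, 1.1)
    t2
  })
  tab <- tree_set_rerun(trees, xo, models = c("BM1", "OU1"))
  expect_gt(median(tab$weight[tab$model == "OU1"]), 0.5)
  bad <- tr
  bad$tip.label[1] <- "not_a_specimen"
  expect_error(tree_set_rerun(list(bad), xo), "not_a_specimen")
})
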