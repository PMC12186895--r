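test_that("anatomical references pass through generator truth and obey Z order", {
  m <- make_bone(bone_params(), n_axial = 24, n_radial = 24)
  refs <- locate_refs(m)
  expect_gt(refs$proximal_point[3], refs$distal_point[3])
  expect_equal(refs$crest_point, unname(m$vertices[m$crest_vertex, ]))
  expect_setequal(refs$head_vertices, m$head_vertices)
})

test_that("fallback crest detection finds a radial bump at the right height", {
  # bump at 40% height, no generator truth
  m <- make_bone(bone_params(crest_height_frac = 0.4, crest_amplitude = 0.8),
                 n_axial = 40, n_radial = 32)
  refs <- locate_refs(m, use_truth = FALSE)
  L <- bone_params()$length
  expect_lt(abs(refs$crest_point[3] / L - 0.4), 0.05)
  rad <- sqrt(sum(refs$crest_point[1:2]^2))
  expect_gt(rad, bone_params()$shaft_radius_x) # on the bump, not the shaft
})

test_that("functional length matches generator truth and is isometry-invariant", {
  p <- bone_params(length = 12, curvature = 0.015)
  m <- make_bone(p, n_axial = 32, n_radial = 24)
  refs <- locate_refs(m)
  expect_lt(abs(functional_length(refs) - 12) / 12, 0.02)
  # rigid rotation of both points leaves the distance unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  refs2 <- refs
  refs2$proximal_point <- as.vector(R %*% refs$proximal_point)
  refs2$distal_point <- as.vector(R %*% refs$distal_point)
  expect_equal(functional_length(refs2), functional_length(refs))
  refs3 <- refs
  refs3$distal_point <- refs3$proximal_point
  expect_equal(functional_length(refs3), 0)
})

test_that("sphere fitting recovers exact and noisy centres", {
  set.seed(1)
  ctr <- c(0.3, -0.2, 9)
  rho <- 1.4
  th <- runif(300, 0, 2 * pi)
  ph <- runif(300, 0, pi / 2)
  pts <- cbind(ctr[1] + rho * cos(th) * cos(ph),
               ctr[2] + rho * sin(th) * cos(ph),
               ctr[3] + rho * sin(ph))
  mesh <- bone_mesh(rbind(pts, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    matrix(c(301, 302, 303), 1))
  fit <- center_of_rotation(mesh, seq_len(300))
  expect_lt(sqrt(sum((fit - ctr)^2)), 1e-6 * rho)
  expect_lt(abs(attr(fit, "radius") - rho), 1e-6 * rho)
  # 1% radial noise: centre recovered within 3% of rho
  noisy <- pts + matrix(rnorm(900, sd = 0.01 * rho), ncol = 3)
  mesh2 <- bone_mesh(rbind(noisy, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     matrix(c(301, 302, 303), 1))
  fit2 <- center_of_rotation(mesh2, seq_len(300))
  expect_lt(sqrt(sum((fit2 - ctr)^2)), 0.03 * rho)
  # generator bone: within 5% of the stored cap centre
  m <- make_bone(bone_params(), n_axial = 24, n_radial = 24)
  cor_fit <- center_of_rotation(m, m$head_vertices)
  expect_lt(sqrt(sum((cor_fit - m$head_center)^2)), 0.05 * m$head_radius)
})

test_that("gyration performance is the inverse normalised radius of gyration", {
  com <- c(0, 0, 4)
  cor <- c(0, 0, 9)
  expect_equal(gyration_perf(com, cor, 10), 2)
  expect_equal(gyration_perf(2 * com, 2 * cor, 20), 2) # scale invariance
  expect_error(gyration_perf(com, com, 10), "undefined")
})

test_that("torsion performance hits the sine of the generator twist", {
  for (deg in c(0, 30, 90)) {
    m <- make_bone(bone_params(torsion_deg = deg), n_axial = 40, n_radial = 36)
    refs <- locate_refs(m)
    cs <- slice_contours(m)
    shaft <- cs[vapply(cs, `[[`, 0, "z") <= refs$head_base_z]
    expect_lt(abs(torsion_perf(shaft) - sin(deg * pi / 180)), 0.05)
  }
})

test_that("near-circular end contours warn but still return a torsion value", {
  circ1 <- circle_contour(r = 1, z = 0)
  circ2 <- circle_contour(r = 1, z = 5)
  expect_warning(v <- torsion_perf(list(circ1, circ2)), "near-circular")
  expect_true(is.finite(v))
})

test_that("muscle levers follow the perpendicular-distance definitions", {
  a <- 2; L <- 10
  refs <- list(crest_point = c(0, a, a) + c(1, 1, 1))
  lev <- muscle_levers(refs, cor = c(1, 1, 1), length = L, centroid_size = 4)
  expect_equal(lev$lever_x, a * sqrt(2)) # d = (0, a, a)
  expect_equal(lev$lever_y, a)
  expect_equal(lev$swing_force, (a * sqrt(2) + a) / (2 * L))
  # crest in the YZ plane (d_x = 0): lever_z = d_y exactly
  refs2 <- list(crest_point = c(0, 3, 2))
  lev2 <- muscle_levers(refs2, cor = c(0, 0, 0), length = L, centroid_size = 4)
  expect_equal(lev2$lever_z, 3)
  expect_equal(lev2$spin_lever, 3 / 4)
  # exactly on the +Y axis at the COR's height the Y lever degenerates
  expect_error(muscle_levers(list(crest_point = c(0, 3, 0)), cor = c(0, 0, 0),
                             length = L, centroid_size = 4), "zero muscle lever")
})

test_that("swing speed times swing force respects the AM-HM inequality", {
  set.seed(7)
  for (i in 1:50) {
    d <- rnorm(3)
    if (any(abs(d) < 1e-3)) next
    lev <- muscle_levers(list(crest_point = d), cor = c(0, 0, 0),
                         length = 1, centroid_size = 1)
    expect_gte(lev$swing_speed * lev$swing_force, 1 - 1e-12)
  }
  # equality iff the two per-axis force advantages are equal
  lev_eq <- muscle_levers(list(crest_point = c(1, 1, 4)), cor = c(0, 0, 0),
                          length = 1, centroid_size = 1)
  expect_equal(lev_eq$swing_speed * lev_eq$swing_force, 1)
})

test_that("strength performance is the size-normalised fourth root of mean I_x", {
  secs <- list(list(I_x = 16), list(I_x = 16))
  expect_equal(strength_perf(secs, 2), 1)
  expect_equal(strength_perf(list(list(I_x = 81)), 3), 1)
  # isotropic scaling by s: I_x ~ s^4, centroid size ~ s -> invariant
  circ <- circle_contour(r = 1, n = 128)
  big <- circ; big$points <- 3 * big$points
  s1 <- strength_perf(list(cross_section_properties(circ)), 1)
  s2 <- strength_perf(list(cross_section_properties(big)), 3)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("trait tables are min-max scaled with both endpoints attained", {
  tt <- small_traits()
  by_trait <- split(tt$scaled, tt$trait)
  for (v in by_trait) {
    expect_equal(min(v), 0)
    expect_equal(max(v), 1)
  }
  # two specimens: every scaled column is exactly {0, 1}
  two <- build_trait_table(list(
    a = make_bone(bone_params(torsion_deg = 5), n_axial = 24, n_radial = 24),
    b = make_bone(bone_params(torsion_deg = 50, length = 12), n_axial = 24, n_radial = 24)
  ))
  expect_true(all(sort(unique(two$scaled)) == c(0, 1)))
})

test_that("duplicating a specimen leaves the others' scaled values unchanged", {
  m1 <- make_bone(bone_params(torsion_deg = 5), n_axial = 24, n_radial = 24)
  m2 <- make_bone(bone_params(torsion_deg = 50, length = 12), n_axial = 24, n_radial = 24)
  m3 <- make_bone(bone_params(torsion_deg = 25), n_axial = 24, n_radial = 24)
  t3 <- build_trait_table(list(a = m1, b = m2, c = m3))
  t4 <- build_trait_table(list(a = m1, b = m2, c = m3, c2 = m3))
  for (sp in c("a", "b", "c")) {
    expect_equal(t4$scaled[t4$specimen == sp], t3$scaled[t3$specimen == sp])
  }
})

test_that("measured torsion tracks set torsion monotonically across a sample", {
  set <- small_set()
  tt <- small_traits()
  true_sin <- vapply(set$specimens$params,
                     function(p) sin(p$torsion_deg * pi / 180), 0)
  got <- tt$raw[tt$trait == "torsion"]
  expect_gte(cor(got, true_sin, method = "spearman"), 0.95)
})
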