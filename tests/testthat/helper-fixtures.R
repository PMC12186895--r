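# Shared fixtures, built once per test run and memoised.
fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# three-posture synthetic sample: sprawling / parasagittal / unknown
small_groups <- function() default_groups()[c("herptile", "therian", "fossil")]

small_set <- function() memo("small_set", {
  make_dataset(small_groups(), n_per_group = 5, with_tree = TRUE, seed = 42,
               n_axial = 32, n_radial = 28)
})

small_traits <- function() memo("small_traits", build_trait_table(small_set()))

small_proc <- function() memo("small_proc", {
  set <- small_set()
  lms <- purrr::map2_dfr(set$specimens$mesh, set$specimens$id, function(m, id) {
    landmark_bone(m, specimen_id = id)
  })
  gpa(lms)
})

small_ms <- function() memo("small_ms", {
  bgpca(small_proc(), small_set()$specimens$posture)
})

small_surfaces <- function() memo("small_surfaces", {
  ms <- small_ms()
  grid <- grid_spec(ms, n_x = 30, n_y = 30)
  trait_surfaces(small_traits(), ms, grid = grid)
})

# simple closed box mesh for geometry oracles
box_mesh <- function(center = c(0, 0, 0), size = c(1, 1, 1)) {
  h <- size / 2
  v <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                             z = c(-h[3], h[3])))
  v <- sweep(v, 2, center, "+")
  # 12 outward-oriented triangles of the unit box (vertex order from expand.grid)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # bottom (z-)
    c(5, 6, 7), c(6, 8, 7),   # top (z+)
    c(1, 2, 5), c(2, 6, 5),   # front (y-)
    c(3, 7, 4), c(4, 7, 8),   # back (y+)
    c(1, 5, 3), c(3, 5, 7),   # left (x-)
    c(2, 4, 6), c(4, 8, 6)    # right (x+)
  )
  bone_mesh(v, f)
}

# open-ended circular cylinder with flat cap fans, along Z from 0 to L
cylinder_mesh <- function(radius = 1, L = 10, n_axial = 24, n_radial = 64) {
  theta <- seq(0, 2 * pi, length.out = n_radial + 1)[-(n_radial + 1)]
  zs <- seq(0, L, length.out = n_axial)
  rings <- lapply(zs, function(z) cbind(radius * cos(theta), radius * sin(theta), z))
  verts <- rbind(c(0, 0, 0), do.call(rbind, rings), c(0, 0, L))
  ring_idx <- function(i) 1L + (i - 1L) * n_radial + seq_len(n_radial)
  jn <- c(seq_len(n_radial)[-1], 1L)
  apex <- nrow(verts)
  faces <- list(cbind(1L, ring_idx(1)[jn], ring_idx(1)))
  for (i in seq_len(n_axial - 1)) {
    lo <- ring_idx(i); hi <- ring_idx(i + 1)
    faces[[i + 1]] <- rbind(cbind(lo, lo[jn], hi), cbind(lo[jn], hi[jn], hi))
  }
  faces[[n_axial + 1]] <- cbind(ring_idx(n_axial), ring_idx(n_axial)[jn], apex)
  bone_mesh(verts, do.call(rbind, faces))
}

circle_contour <- function(r = 1, n = 256, z = 0.5, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  structure(list(z = z, points = cbind(center[1] + r * cos(th),
                                       center[2] + r * sin(th)),
                 area = pi * r^2),
            class = "bone_contour")
}

square_contour <- function(half = 1, z = 0) {
  structure(list(z = z,
                 points = rbind(c(-half, -half), c(half, -half),
                                c(half, half), c(-half, half)),
                 area = (2 * half)^2),
            class = "bone_contour")
}

# mean silhouette width on 2D scores
silhouette_mean <- function(xy, groups) {
  d <- as.matrix(dist(xy))
  n <- nrow(xy)
  s <- vapply(seq_len(n), function(i) {
    own <- groups == groups[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(groups), groups[i]), function(g) {
      mean(d[i, groups == g])
    }, 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}
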