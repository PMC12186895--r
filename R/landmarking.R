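#' Check mesh alignment against the global Z axis
#'
#' Reports the angle between the mesh's principal axis (leading eigenvector of
#' the vertex covariance) and global Z, and the rotation that would realign
#' it. The mesh is never modified.
#'
#' @param mesh a `bone_mesh`.
#' @param tol_deg pass tolerance in degrees.
#' @return A list with `angle_deg`, `pass`, and `rotation` (a 3x3 matrix `R`
#'   such that `vertices %*% R` puts the principal axis on Z).
#' @export
check_alignment <- function(mesh, tol_deg = 5) {
  v <- mesh$vertices
  if (nrow(v) < 4 || any(apply(v, 2, stats::sd) == 0) && diff(range(v[, 3])) == 0) {
    stop("degenerate mesh: zero extent")
  }
  ctr <- colMeans(v)
  ev <- eigen(stats::cov(v), symmetric = TRUE)
  main <- ev$vectors[, 1]
  if (main[3] < 0) main <- -main
  angle <- acos(pmin(1, abs(main[3]))) * 180 / pi
  # rotation sending (e2, e3, e1) -> (x, y, z), det forced to +1
  E <- ev$vectors
  if (E[3, 1] < 0) E[, 1] <- -E[, 1]
  R <- E[, c(2, 3, 1)]
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(angle_deg = angle, pass = angle <= tol_deg, rotation = R, center = ctr)
}

#' Apply an alignment rotation to a mesh
#'
#' @param mesh a `bone_mesh`.
#' @param rotation 3x3 rotation matrix (columns orthonormal), typically from
#'   [check_alignment()].
#' @return The rotated `bone_mesh` (rotated about the vertex centroid).
#' @export
rotate_mesh <- function(mesh, rotation) {
  ctr <- colMeans(mesh$vertices)
  mesh$vertices <- sweep(mesh$vertices, 2, ctr) %*% rotation
  mesh$vertices <- sweep(mesh$vertices, 2, ctr, "+")
  mesh
}

#' Slice a mesh into planar contours
#'
#' Cuts the mesh with planes normal to Z at `n_slices` evenly spaced fractions
#' of the Z extent over `span`. Plane-edge intersections are computed once per
#' unique mesh edge, so contour chaining is exact (integer edge keys). When a
#' plane yields several closed loops the largest-area loop is kept. Contours
#' are returned counterclockwise viewed from +Z.
#'
#' @param mesh a `bone_mesh`, watertight over the sliced span.
#' @param n_slices number of slicing planes (default 21).
#' @param span `(low, high)` fractions of the Z extent to slice over.
#' @return A list of `bone_contour` objects (fields `z`, `points` (closed
#'   polygon as an n x 2 matrix, no repeated last point), `area`).
#' @export
slice_contours <- function(mesh, n_slices = 21, span = c(0.01, 0.99)) {
  v <- mesh$vertices
  zr <- range(v[, 3])
  fracs <- seq(span[1], span[2], length.out = n_slices)
  heights <- zr[1] + fracs * diff(zr)
  # unique undirected edges and the faces that use them
  f <- mesh$faces
  e_all <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e_key <- paste(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  ue <- !duplicated(e_key)
  edges <- cbind(pmin(e_all[ue, 1], e_all[ue, 2]), pmax(e_all[ue, 1], e_all[ue, 2]))
  edge_id <- match(e_key, e_key[ue])
  face_edges <- matrix(edge_id, ncol = 3) # per face: edge ids of its 3 edges
  out <- lapply(seq_along(heights), function(i) {
    ct <- contour_at(v, edges, face_edges, heights[i], zr)
    if (is.null(ct)) stop("empty mesh intersection at plane z = ", heights[i])
    ct
  })
  out
}

contour_at <- function(v, edges, face_edges, h, zr) {
  tolz <- 1e-9 * diff(zr)
  za <- v[edges[, 1], 3]
  zb <- v[edges[, 2], 3]
  # nudge the plane off any vertex it hits exactly
  while (any(abs(za - h) < tolz) || any(abs(zb - h) < tolz)) h <- h + 2 * tolz
  cross <- (za - h) * (zb - h) < 0
  if (!any(cross)) return(NULL)
  t <- (h - za[cross]) / (zb[cross] - za[cross])
  pa <- v[edges[cross, 1], , drop = FALSE]
  pb <- v[edges[cross, 2], , drop = FALSE]
  pts <- pa + t * (pb - pa) # n_cross x 3
  cross_id <- which(cross)
  local <- match(seq_len(nrow(edges)), cross_id) # edge id -> crossing row
  fe <- matrix(local[face_edges], ncol = 3)
  nhit <- rowSums(!is.na(fe))
  segs <- t(apply(fe[nhit == 2, , drop = FALSE], 1, function(r) r[!is.na(r)]))
  if (!nrow(segs)) return(NULL)
  loops <- chain_segments(segs)
  polys <- lapply(loops, function(ids) pts[ids, 1:2, drop = FALSE])
  areas <- vapply(polys, function(p) abs(polygon_area(p)), 0)
  best <- which.max(areas)
  poly <- clean_polygon(polys[[best]], tol = 1e-8 * diff(zr))
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  structure(list(z = h, points = poly, area = abs(polygon_area(poly))),
            class = "bone_contour")
}

# Chain crossing-point segments (pairs of crossing ids) into closed loops.
chain_segments <- function(segs) {
  n <- max(segs)
  adj <- vector("list", n)
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, 1]; b <- segs[s, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  used <- logical(n)
  loops <- list()
  for (start in seq_len(n)) {
    if (used[start] || is.null(adj[[start]])) next
    loop <- start
    used[start] <- TRUE
    cur <- start
    repeat {
      nxt <- adj[[cur]][!used[adj[[cur]]]]
      if (!length(nxt)) break
      cur <- nxt[1]
      used[cur] <- TRUE
      loop <- c(loop, cur)
    }
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  loops
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

clean_polygon <- function(p, tol) {
  keep <- rep(TRUE, nrow(p))
  nxt <- c(seq_len(nrow(p))[-1], 1L)
  d <- sqrt(rowSums((p[nxt, , drop = FALSE] - p)^2))
  keep[d < tol] <- FALSE
  if (sum(keep) < 3) return(p)
  p[keep, , drop = FALSE]
}

#' Cross-sectional properties of a contour
#'
#' Exact polygon (Green's theorem) formulas for area, centroid, and the second
#' moments of area about centroidal axes parallel to global X and Y, assuming
#' a solid section. `J = I_x + I_y` by definition.
#'
#' @param contour a `bone_contour` (or an n x 2 matrix taken as a closed
#'   polygon).
#' @return A list of class `cross_section`: `area`, `centroid`, `I_x`, `I_y`,
#'   `I_xy`, `J`.
#' @export
cross_section_properties <- function(contour) {
  p <- if (inherits(contour, "bone_contour")) contour$points else as.matrix(contour)
  if (polygon_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (A <= 0) stop("degenerate contour: non-positive area")
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  Ix0 <- sum((y^2 + y * yn + yn^2) * cr) / 12   # about global X through origin
  Iy0 <- sum((x^2 + x * xn + xn^2) * cr) / 12
  Ixy0 <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  Ix <- Ix0 - A * cy^2
  Iy <- Iy0 - A * cx^2
  Ixy <- Ixy0 - A * cx * cy
  structure(list(area = A, centroid = c(cx, cy), I_x = Ix, I_y = Iy,
                 I_xy = Ixy, J = Ix + Iy),
            class = "cross_section")
}

#' Place equidistant landmarks on a contour
#'
#' Resamples the contour at `n_points` positions equally spaced by arc length,
#' starting where the ray from the contour's area centroid along +X crosses
#' the outline (the outermost crossing for non-convex contours), proceeding
#' counterclockwise viewed from +Z. Points are lifted to 3D with the slice's
#' Z.
#'
#' @param contour a `bone_contour`.
#' @param n_points landmarks per contour (default 24).
#' @return An `n_points` x 3 matrix.
#' @export
landmark_contour <- function(contour, n_points = 24) {
  p <- contour$points
  if (nrow(p) < 3) stop("degenerate contour")
  ctr <- cross_section_properties(contour)$centroid
  # crossings of the +X ray from the centroid
  y0 <- ctr[2]
  nxt <- c(seq_len(nrow(p))[-1], 1L)
  ya <- p[, 2] - y0; yb <- p[nxt, 2] - y0
  hit <- (ya <= 0 & yb > 0) | (ya > 0 & yb <= 0)
  tt <- -ya[hit] / (yb[hit] - ya[hit])
  xs <- p[hit, 1] + tt * (p[nxt[hit], 1] - p[hit, 1])
  ok <- xs > ctr[1]
  if (!any(ok)) stop("contour does not cross the +X ray from its centroid")
  hit_rows <- which(hit)
  sel <- hit_rows[ok][which.max(xs[ok])]
  tstar <- tt[match(sel, hit_rows)]
  start <- p[sel, ] + tstar * (p[nxt[sel], ] - p[sel, ])
  # reorder vertices to start just after the start point
  seq_ids <- c(nxt[sel]:nrow(p), if (nxt[sel] > 1) 1:(nxt[sel] - 1))
  ring <- rbind(start, p[seq_ids, , drop = FALSE], start)
  d <- sqrt(rowSums(diff(ring)^2))
  cum <- c(0, cumsum(d))
  per <- cum[length(cum)]
  if (per <= 0) stop("degenerate contour: zero perimeter")
  target <- per * (seq_len(n_points) - 1) / n_points
  idx <- findInterval(target, cum, rightmost.closed = TRUE)
  frac <- (target - cum[idx]) / pmax(d[idx], .Machine$double.eps)
  pts2 <- ring[idx, , drop = FALSE] + frac * (ring[idx + 1, , drop = FALSE] - ring[idx, , drop = FALSE])
  out <- cbind(pts2, contour$z)
  dimnames(out) <- NULL
  out
}

#' Landmark a whole bone
#'
#' Runs the slice-landmark protocol: `n_slices` contours evenly spaced along
#' the bone's Z extent, `n_per_slice` equidistant landmarks per contour
#' (21 x 24 = 504 by default).
#'
#' @param mesh a `bone_mesh` passing [check_alignment()].
#' @param n_slices,n_per_slice protocol counts.
#' @param span slice span as fractions of the Z extent.
#' @param specimen_id label stored with the landmarks.
#' @param tol_deg alignment tolerance; set `Inf` to skip the check.
#' @return A tibble of class `landmark_set` with columns `specimen`, `slice`,
#'   `index`, `x`, `y`, `z`, and attribute `slice_fractions`.
#' @export
landmark_bone <- function(mesh, n_slices = 21, n_per_slice = 24,
                          span = c(0.01, 0.99), specimen_id = "specimen",
                          tol_deg = 5) {
  if (is.finite(tol_deg)) {
    al <- check_alignment(mesh, tol_deg)
    if (!al$pass) {
      stop(sprintf("mesh fails alignment check (%.1f deg off Z); realign first",
                   al$angle_deg))
    }
  }
  contours <- slice_contours(mesh, n_slices = n_slices, span = span)
  pts <- purrr::map_dfr(seq_along(contours), function(i) {
    lm <- landmark_contour(contours[[i]], n_points = n_per_slice)
    tibble::tibble(specimen = specimen_id, slice = i,
                   index = seq_len(n_per_slice),
                   x = lm[, 1], y = lm[, 2], z = lm[, 3])
  })
  attr(pts, "slice_fractions") <- seq(span[1], span[2], length.out = n_slices)
  class(pts) <- c("landmark_set", class(pts))
  pts
}

#' Write landmark sets as CSV or TPS
#'
#' @param landmarks a `landmark_set` tibble (possibly several specimens bound
#'   together).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  utils::write.csv(as.data.frame(landmarks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
write_landmarks_tps <- function(landmarks, path) {
  specs <- split(landmarks, landmarks$specimen)
  lines <- unlist(lapply(specs, function(s) {
    c(sprintf("LM3=%d", nrow(s)),
      sprintf("%.10g %.10g %.10g", s$x, s$y, s$z),
      sprintf("ID=%s", s$specimen[1]))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
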