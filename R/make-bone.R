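#' Parameters of a synthetic long bone
#'
#' The generator builds a stylised humerus: an elliptical-section shaft aligned
#' to the global Z axis, with end flares, a linear twist of the section's major
#' axis (humeral torsion), a gentle sagittal bow, a Gaussian radial bump
#' standing in for the deltopectoral crest, and a hemispherical articular head
#' capping the proximal end. All parameters are in arbitrary length units
#' except where noted.
#'
#' @param length total bone length (distal pole at z = 0, head apex at z = length).
#' @param shaft_radius_x,shaft_radius_y semi-axes of the shaft ellipse; the
#'   default section is wider along X so the major axis is X at zero torsion.
#' @param proximal_flare,distal_flare end-width multipliers (>= 1).
#' @param torsion_deg twist of the section major axis, degrees in \[0, 180);
#'   zero at the distal end, reaching `torsion_deg` at the base of the head.
#' @param curvature sagittal bow amplitude as a fraction of length.
#' @param crest_height_frac height of the crest apex as a fraction of length,
#'   in (0, 1).
#' @param crest_azimuth_deg azimuth of the crest bump, degrees from +X.
#' @param crest_amplitude relative radial amplitude of the crest bump (>= 0).
#' @param head_radius radius of the hemispherical head cap.
#' @param side `"left"` or `"right"`; a right bone is the exact X-mirror of the
#'   left build.
#' @return A validated list of class `bone_params`.
#' @export
bone_params <- function(length = 10,
                        shaft_radius_x = 0.9,
                        shaft_radius_y = 0.6,
                        proximal_flare = 1.3,
                        distal_flare = 1.5,
                        torsion_deg = 20,
                        curvature = 0.02,
                        crest_height_frac = 0.35,
                        crest_azimuth_deg = 70,
                        crest_amplitude = 0.5,
                        head_radius = 1.2,
                        side = c("left", "right")) {
  side <- match.arg(side)
  p <- list(
    length = length, shaft_radius_x = shaft_radius_x,
    shaft_radius_y = shaft_radius_y, proximal_flare = proximal_flare,
    distal_flare = distal_flare, torsion_deg = torsion_deg,
    curvature = curvature, crest_height_frac = crest_height_frac,
    crest_azimuth_deg = crest_azimuth_deg, crest_amplitude = crest_amplitude,
    head_radius = head_radius, side = side
  )
  validate_bone_params(p)
  structure(p, class = "bone_params")
}

validate_bone_params <- function(p) {
  num <- p[setdiff(names(p), "side")]
  if (any(!vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), TRUE))) {
    stop("bone parameters must be finite scalars")
  }
  pos <- c("length", "shaft_radius_x", "shaft_radius_y", "head_radius")
  if (any(unlist(p[pos]) <= 0)) stop("length, shaft radii and head_radius must be > 0")
  if (p$proximal_flare < 1 || p$distal_flare < 1) stop("flares must be >= 1")
  if (p$torsion_deg < 0 || p$torsion_deg >= 180) stop("torsion_deg must lie in [0, 180)")
  if (p$crest_height_frac <= 0 || p$crest_height_frac >= 1) {
    stop("crest_height_frac must lie in (0, 1)")
  }
  if (p$crest_amplitude < 0) stop("crest_amplitude must be >= 0")
  if (p$head_radius >= p$length / 2) stop("head_radius must be < length/2")
  invisible(p)
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# Twist of the section major axis at height z: linear from 0 (distal) to the
# full torsion angle at the base of the head cap, constant above.
twist_at <- function(z, params) {
  z_eq <- params$length - params$head_radius
  params$torsion_deg * pi / 180 * pmin(pmax(z / z_eq, 0), 1)
}

bow_at <- function(z, params) {
  z_eq <- params$length - params$head_radius
  params$curvature * params$length * sin(pi * pmin(z, z_eq) / params$length)
}

flare_at <- function(z, params) {
  z_eq <- params$length - params$head_radius
  distal <- (params$distal_flare - 1) * smoothstep(1 - z / (0.12 * z_eq))
  proximal <- (params$proximal_flare - 1) * smoothstep((z / z_eq - 0.85) / 0.15)
  1 + distal + proximal
}

crest_bump <- function(azimuth, z, params) {
  sig_theta <- 0.5 # radians
  sig_z <- 0.06 * params$length
  zc <- params$crest_height_frac * params$length
  beta <- params$crest_azimuth_deg * pi / 180
  d <- atan2(sin(azimuth - beta), cos(azimuth - beta)) # wrapped angle diff
  1 + params$crest_amplitude * exp(-d^2 / (2 * sig_theta^2) - (z - zc)^2 / (2 * sig_z^2))
}

# One shaft cross-section ring: twisted flared ellipse plus crest bump,
# offset by the sagittal bow.
shaft_ring <- function(z, theta, params) {
  f <- flare_at(z, params)
  psi <- twist_at(z, params)
  px <- params$shaft_radius_x * f * cos(theta)
  py <- params$shaft_radius_y * f * sin(theta)
  x <- cos(psi) * px - sin(psi) * py
  y <- sin(psi) * px + cos(psi) * py
  g <- crest_bump(atan2(y, x), z, params)
  cbind(x * g, y * g + bow_at(z, params), z)
}

#' Build a synthetic bone mesh
#'
#' Constructs a watertight, outward-oriented triangle mesh from
#' [bone_params()]. The long axis lies along global Z with the distal pole at
#' z = 0 and the head apex at z = `length`. Ground truth is attached to the
#' mesh: the crest apex vertex index, the head-cap centre/radius, and the
#' indices of all vertices lying on the articular sphere.
#'
#' @param params a [bone_params()] object (or plain list with the same fields).
#' @param n_axial number of shaft cross-section stations (>= 8).
#' @param n_radial number of vertices per ring (>= 8).
#' @param seed unused; construction is fully deterministic, the argument is
#'   accepted for interface uniformity with the stochastic generators.
#' @return A `bone_mesh`.
#' @export
#' @examples
#' m <- make_bone(bone_params(torsion_deg = 30), n_axial = 24, n_radial = 24)
#' is_watertight(m)
make_bone <- function(params = bone_params(), n_axial = 48, n_radial = 48,
                      seed = 1L) {
  if (!inherits(params, "bone_params")) params <- do.call(bone_params, params)
  if (n_axial < 8 || n_radial < 8) stop("n_axial and n_radial must be >= 8")
  L <- params$length
  R <- params$head_radius
  z_eq <- L - R
  theta <- seq(0, 2 * pi, length.out = n_radial + 1)[-(n_radial + 1)]
  o_eq <- bow_at(z_eq, params)

  z_shaft <- seq(0, z_eq, length.out = n_axial)
  rings <- lapply(z_shaft, shaft_ring, theta = theta, params = params)

  n_head <- max(6L, ceiling(n_radial / 6))
  phi <- seq(0, pi / 2, length.out = n_head + 1)[seq_len(n_head)]
  head_rings <- lapply(phi, function(ph) {
    r <- R * cos(ph)
    cbind(r * cos(theta), r * sin(theta) + o_eq, z_eq + R * sin(ph))
  })
  rings <- c(rings, head_rings)

  n_rings <- length(rings)
  verts <- rbind(
    c(0, 0, 0),                 # distal pole (vertex 1)
    do.call(rbind, rings),
    c(0, o_eq, L)               # head apex (last vertex)
  )
  ring_idx <- function(i) 1L + (i - 1L) * n_radial + seq_len(n_radial)
  apex <- nrow(verts)

  jn <- c(seq_len(n_radial)[-1], 1L) # j + 1 mod n
  faces <- vector("list", n_rings + 1)
  r1 <- ring_idx(1)
  faces[[1]] <- cbind(1L, r1[jn], r1) # distal fan, normal -Z
  for (i in seq_len(n_rings - 1)) {
    lo <- ring_idx(i)
    hi <- ring_idx(i + 1)
    faces[[i + 1]] <- rbind(
      cbind(lo, lo[jn], hi),
      cbind(lo[jn], hi[jn], hi)
    )
  }
  rt <- ring_idx(n_rings)
  faces[[n_rings + 1]] <- cbind(rt, rt[jn], apex) # apex fan, normal +Z

  mesh <- bone_mesh(
    verts, do.call(rbind, faces),
    params = params,
    side = "left",
    head_center = c(0, o_eq, z_eq),
    head_radius = R,
    head_vertices = c((1L + n_axial * n_radial + 1L):(1L + n_rings * n_radial), apex),
    crest_vertex = crest_apex_index(verts, params, n_axial, n_radial, z_shaft)
  )
  if (identical(params$side, "right")) mesh <- mirror_mesh(mesh)
  mesh
}

# Index of the generator's crest apex: the vertex on the station nearest the
# crest height whose radial distance from the bow axis is maximal.
crest_apex_index <- function(verts, params, n_axial, n_radial, z_shaft) {
  zc <- params$crest_height_frac * params$length
  i <- which.min(abs(z_shaft - zc))
  idx <- 1L + (i - 1L) * n_radial + seq_len(n_radial)
  ring <- verts[idx, , drop = FALSE]
  rad <- sqrt(ring[, 1]^2 + (ring[, 2] - bow_at(z_shaft[i], params))^2)
  idx[which.max(rad)]
}
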