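#' Locate anatomical reference features on a bone mesh
#'
#' Returns the proximal-most and distal-most points, the articular-head vertex
#' set, and the deltopectoral-crest apex. When the mesh carries generator
#' ground truth (and `use_truth = TRUE`) the stored head cap and crest apex
#' are used; otherwise the head is taken as the top `head_frac` of the Z
#' extent and the crest as the vertex of maximal radial (XY) distance from the
#' Z axis within `crest_window` of the Z extent.
#'
#' @param mesh an aligned `bone_mesh`.
#' @param use_truth use generator annotations when present.
#' @param head_frac fallback head region as a fraction of Z extent.
#' @param crest_window fallback crest search window (fractions of Z extent).
#' @return A list of class `anatomical_refs`: `proximal_point`, `distal_point`,
#'   `head_vertices` (indices), `crest_point`, `head_base_z`.
#' @export
locate_refs <- function(mesh, use_truth = TRUE, head_frac = 0.15,
                        crest_window = c(0.1, 0.6)) {
  v <- mesh$vertices
  zr <- range(v[, 3])
  ext <- diff(zr)
  proximal <- v[which.max(v[, 3]), ]
  distal <- v[which.min(v[, 3]), ]
  if (use_truth && !is.null(mesh$head_vertices)) {
    head_idx <- mesh$head_vertices
  } else {
    head_idx <- which(v[, 3] >= zr[2] - head_frac * ext)
  }
  if (!length(head_idx)) stop("empty head-vertex candidate set")
  if (use_truth && !is.null(mesh$crest_vertex)) {
    crest <- v[mesh$crest_vertex, ]
  } else {
    zlo <- zr[1] + crest_window[1] * ext
    zhi <- zr[1] + crest_window[2] * ext
    cand <- which(v[, 3] >= zlo & v[, 3] <= zhi)
    if (!length(cand)) stop("empty crest candidate set")
    rad <- sqrt(v[cand, 1]^2 + v[cand, 2]^2)
    crest <- v[cand[which.max(rad)], ]
  }
  structure(
    list(proximal_point = unname(proximal), distal_point = unname(distal),
         head_vertices = head_idx, crest_point = unname(crest),
         head_base_z = min(v[head_idx, 3])),
    class = "anatomical_refs"
  )
}

#' Functional bone length
#'
#' Euclidean distance between the proximal-most articular point and the
#' distal-most condylar point.
#'
#' @param refs an [locate_refs()] result.
#' @return Numeric scalar.
#' @export
functional_length <- function(refs) {
  sqrt(sum((refs$proximal_point - refs$distal_point)^2))
}

#' Centre of rotation by sphere fit to the articular head
#'
#' Least-squares sphere fit: algebraic (linear) solution followed by
#' Gauss-Newton refinement of the geometric distance.
#'
#' @param mesh a `bone_mesh`.
#' @param head_vertices indices of articular-surface vertices (>= 10).
#' @return Length-3 centre; the fitted radius is attached as attribute
#'   `radius`.
#' @export
center_of_rotation <- function(mesh, head_vertices) {
  p <- mesh$vertices[head_vertices, , drop = FALSE]
  if (nrow(p) < 10) stop("need >= 10 head vertices for a sphere fit")
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  qa <- qr(A)
  if (qa$rank < 4) stop("degenerate (coplanar) head vertices: sphere fit failed")
  sol <- qr.coef(qa, b)
  ctr <- sol[1:3]
  r <- sqrt(sol[4] + sum(ctr^2))
  for (it in 1:10) { # geometric refinement
    d <- sweep(p, 2, ctr)
    dist <- sqrt(rowSums(d^2))
    res <- dist - r
    J <- cbind(-d / dist, -1)
    step <- tryCatch(qr.coef(qr(J), res), error = function(e) rep(0, 4))
    step[is.na(step)] <- 0
    ctr <- ctr - step[1:3]
    r <- r - step[4]
    if (sqrt(sum(step^2)) < 1e-12 * max(r, 1)) break
  }
  structure(unname(ctr), radius = r)
}

#' Radius-of-gyration performance
#'
#' The radius of gyration proxy is the distance between the solid centre of
#' mass and the articular centre of rotation, normalised by length; lower is
#' better for inertia, so the inverse is returned: `length / |com - cor|`.
#'
#' @param com,cor 3D points.
#' @param length functional length (> 0).
#' @return Numeric scalar.
#' @export
gyration_perf <- function(com, cor, length) {
  if (length <= 0) stop("length must be > 0")
  r <- sqrt(sum((com - cor)^2))
  if (r == 0) stop("undefined trait: center of mass equals center of rotation")
  length / r
}

# principal-axis angle (mod pi) of a contour's area distribution
contour_axis <- function(contour) {
  cs <- cross_section_properties(contour)
  M <- matrix(c(cs$I_y, cs$I_xy, cs$I_xy, cs$I_x), 2, 2) # area covariance * A
  ev <- eigen(M, symmetric = TRUE)
  v <- ev$vectors[, 1]
  list(angle = atan2(v[2], v[1]) %% pi,
       ratio = sqrt(max(ev$values[1], 0) / max(ev$values[2], 1e-300)))
}

#' Humeral torsion performance
#'
#' Angle between the major principal axes (XY projection) of the distal-most
#' and proximal-most contours, taken in \[0, 180) degrees; returns the sine of
#' that angle. Near-circular end contours (axis ratio < 1.05) trigger a
#' warning but the axis is used anyway.
#'
#' @param contours list of `bone_contour`, ordered along Z (>= 2).
#' @return Numeric in \[0, 1\].
#' @export
torsion_perf <- function(contours) {
  if (length(contours) < 2) stop("need >= 2 contours")
  zs <- vapply(contours, `[[`, 0, "z")
  a_dist <- contour_axis(contours[[which.min(zs)]])
  a_prox <- contour_axis(contours[[which.max(zs)]])
  if (a_dist$ratio < 1.05 || a_prox$ratio < 1.05) {
    warning("near-circular end contour: torsion axis poorly defined")
  }
  delta <- (a_prox$angle - a_dist$angle) %% pi
  abs(sin(delta))
}

#' Muscle leverage of the deltopectoral crest
#'
#' The in-lever is the crest apex's perpendicular distance to the axis lines
#' through the centre of rotation. X/Y-axis levers over functional length give
#' force advantages (their mean = `swing_force`); the mean of their inverses is
#' the velocity advantage `swing_speed`; the Z-axis lever over centroid size is
#' the long-axis `spin_lever`.
#'
#' @param refs an [locate_refs()] result (uses `crest_point`).
#' @param cor centre of rotation.
#' @param length functional length (> 0).
#' @param centroid_size specimen centroid size (> 0).
#' @return Named list `swing_force`, `swing_speed`, `spin_lever` plus the raw
#'   per-axis levers.
#' @export
muscle_levers <- function(refs, cor, length, centroid_size) {
  if (length <= 0 || centroid_size <= 0) stop("length and centroid_size must be > 0")
  d <- refs$crest_point - cor
  lever_x <- sqrt(d[2]^2 + d[3]^2)
  lever_y <- sqrt(d[1]^2 + d[3]^2)
  lever_z <- sqrt(d[1]^2 + d[2]^2)
  if (lever_x == 0 || lever_y == 0 || lever_z == 0) {
    stop("undefined trait: zero muscle lever")
  }
  force_x <- lever_x / length
  force_y <- lever_y / length
  list(
    swing_force = (force_x + force_y) / 2,
    swing_speed = (1 / force_x + 1 / force_y) / 2,
    spin_lever = lever_z / centroid_size,
    lever_x = lever_x, lever_y = lever_y, lever_z = lever_z
  )
}

#' Bending-strength performance
#'
#' Fourth root of the slice-averaged second moment of area about X, divided by
#' centroid size (dimensionless by construction).
#'
#' @param sections list of [cross_section_properties()] results (>= 1).
#' @param centroid_size specimen centroid size (> 0).
#' @return Numeric scalar.
#' @export
strength_perf <- function(sections, centroid_size) {
  if (!length(sections)) stop("need >= 1 cross-section")
  if (centroid_size <= 0) stop("centroid_size must be > 0")
  mean(vapply(sections, `[[`, 0, "I_x"))^0.25 / centroid_size
}

trait_names <- function() {
  c("length", "gyration", "torsion", "swing_force", "swing_speed",
    "spin", "strength")
}

# all seven raw traits for one mesh
measure_specimen <- function(mesh, n_slices = 21, n_per_slice = 24,
                             span = c(0.01, 0.99), use_truth = TRUE) {
  refs <- locate_refs(mesh, use_truth = use_truth)
  lm <- landmark_bone(mesh, n_slices, n_per_slice, span = span, tol_deg = Inf)
  cs <- centroid_size(lm)
  contours <- slice_contours(mesh, n_slices = n_slices, span = span)
  len <- functional_length(refs)
  com <- center_of_mass(mesh)
  cor <- center_of_rotation(mesh, refs$head_vertices)
  shaft <- contours[vapply(contours, `[[`, 0, "z") <= refs$head_base_z]
  if (length(shaft) < 2) shaft <- contours
  sections <- lapply(contours, cross_section_properties)
  lev <- muscle_levers(refs, cor, len, cs)
  tors <- withCallingHandlers(
    torsion_perf(shaft),
    warning = function(w) invokeRestart("muffleWarning")
  )
  list(
    centroid_size = cs,
    traits = c(
      length = len / cs,
      gyration = gyration_perf(com, cor, len),
      torsion = tors,
      swing_force = lev$swing_force,
      swing_speed = lev$swing_speed,
      spin = lev$spin_lever,
      strength = strength_perf(sections, cs)
    )
  )
}

#' Compute the trait table for a specimen set
#'
#' Measures the seven functional traits on every specimen and min-max scales
#' each trait to \[0, 1\] across the sample (0 = lowest, 1 = highest measured
#' performance). Torsion is measured on the sub-head (diaphyseal) contours,
#' whose principal axes carry the twist; sections through the articular cap
#' are near-circular.
#'
#' @param set a `specimen_set` (or a plain list of `bone_mesh`).
#' @param n_slices,n_per_slice,span landmark-protocol settings.
#' @param use_truth use generator annotations for the head/crest when present.
#' @return A tibble of class `trait_table` (long format): `specimen`, `group`,
#'   `posture`, `centroid_size`, `trait`, `raw`, `scaled`.
#' @export
build_trait_table <- function(set, n_slices = 21, n_per_slice = 24,
                              span = c(0.01, 0.99), use_truth = TRUE) {
  if (inherits(set, "specimen_set")) {
    meshes <- set$specimens$mesh
    ids <- set$specimens$id
    groups <- set$specimens$group
    postures <- set$specimens$posture
  } else {
    meshes <- set
    ids <- names(set) %||% sprintf("specimen_%02d", seq_along(set))
    groups <- rep(NA_character_, length(set))
    postures <- rep(NA_character_, length(set))
  }
  if (length(meshes) < 2) stop("need >= 2 specimens to build a trait table")
  rows <- purrr::map_dfr(seq_along(meshes), function(i) {
    m <- measure_specimen(meshes[[i]], n_slices, n_per_slice, span, use_truth)
    tibble::tibble(
      specimen = ids[i], group = groups[i], posture = postures[i],
      centroid_size = m$centroid_size,
      trait = factor(names(m$traits), levels = trait_names()),
      raw = unname(m$traits)
    )
  })
  out <- rows |>
    dplyr::group_by(.data$trait) |>
    dplyr::mutate(scaled = minmax_scale(.data$raw)) |>
    dplyr::ungroup()
  class(out) <- c("trait_table", class(out))
  out
}

minmax_scale <- function(x) {
  rg <- range(x)
  if (diff(rg) == 0) {
    warning("constant trait column: scaled values set to 0.5")
    return(rep(0.5, length(x)))
  }
  (x - rg[1]) / diff(rg)
}

#' Wide matrix view of a trait table
#'
#' @param trait_table a [build_trait_table()] result.
#' @param value `"scaled"` or `"raw"`.
#' @return A tibble, one row per specimen, one column per trait.
#' @export
trait_matrix <- function(trait_table, value = c("scaled", "raw")) {
  value <- match.arg(value)
  trait_table |>
    dplyr::select("specimen", "trait", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "trait", values_from = dplyr::all_of(value))
}

#' Write a trait table as CSV (wide; raw and scaled columns)
#'
#' @param trait_table a [build_trait_table()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(trait_table, path) {
  meta <- trait_table |>
    dplyr::distinct(.data$specimen, .data$group, .data$posture, .data$centroid_size)
  wide_raw <- trait_matrix(trait_table, "raw")
  names(wide_raw)[-1] <- paste0("raw_", names(wide_raw)[-1])
  wide_sc <- trait_matrix(trait_table, "scaled")
  names(wide_sc)[-1] <- paste0("scaled_", names(wide_sc)[-1])
  out <- meta |>
    dplyr::left_join(wide_raw, by = "specimen") |>
    dplyr::left_join(wide_sc, by = "specimen")
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(path)
}
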