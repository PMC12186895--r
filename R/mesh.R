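#' Triangle-mesh container
#'
#' A `bone_mesh` is a minimal closed triangle surface: an `n x 3` matrix of
#' vertex coordinates and an `m x 3` integer matrix of 1-based face indices,
#' oriented so that face windings point outwards (positive enclosed volume).
#' Generator meshes carry ground-truth annotations (crest apex vertex, head-cap
#' centre and radius, the parameters that built them) used by downstream
#' trait measurements when available.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param ... further named attributes stored on the mesh (e.g. `params`,
#'   `crest_vertex`, `head_center`, `head_radius`, `head_vertices`).
#' @return An object of class `bone_mesh`.
#' @export
bone_mesh <- function(vertices, faces, ...) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (any(!is.finite(vertices))) stop("mesh vertices must be finite")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(
    c(list(vertices = vertices, faces = faces), list(...)),
    class = "bone_mesh"
  )
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat(sprintf(
    "<bone_mesh: %d vertices, %d faces, z in [%.3g, %.3g]>\n",
    nrow(x$vertices), nrow(x$faces),
    min(x$vertices[, 3]), max(x$vertices[, 3])
  ))
  invisible(x)
}

#' Test whether a mesh is watertight and consistently oriented
#'
#' Every undirected edge must be used by exactly two faces, once in each
#' direction.
#'
#' @param mesh a `bone_mesh`.
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key_dir <- paste(he[, 1], he[, 2])
  key_undir <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  all(table(key_undir) == 2L) && !anyDuplicated(key_dir)
}

#' Signed volume enclosed by a mesh
#'
#' Divergence-theorem sum of signed tetrahedra against the origin; positive
#' for outward-oriented closed surfaces.
#'
#' @param mesh a `bone_mesh`.
#' @return Numeric scalar volume.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  # scalar triple product a . (b x c)
  cx <- b[, 2] * c3[, 3] - b[, 3] * c3[, 2]
  cy <- b[, 3] * c3[, 1] - b[, 1] * c3[, 3]
  cz <- b[, 1] * c3[, 2] - b[, 2] * c3[, 1]
  sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
}

#' Centre of mass of a solid mesh
#'
#' Uniform-density solid centroid via signed-tetrahedron summation; the mesh
#' must be watertight.
#'
#' @param mesh a `bone_mesh`.
#' @return Length-3 numeric vector.
#' @export
center_of_mass <- function(mesh) {
  if (!is_watertight(mesh)) stop("center_of_mass() needs a watertight mesh")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  cx <- b[, 2] * c3[, 3] - b[, 3] * c3[, 2]
  cy <- b[, 3] * c3[, 1] - b[, 1] * c3[, 3]
  cz <- b[, 1] * c3[, 2] - b[, 2] * c3[, 1]
  w <- (a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6 # signed tet volumes
  vol <- sum(w)
  if (abs(vol) < .Machine$double.eps * 100) stop("degenerate mesh volume")
  # centroid of each tet (origin apex) is (a + b + c)/4
  ctr <- (a + b + c3) / 4
  unname(colSums(ctr * w) / vol)
}

#' Mirror a mesh across the YZ plane
#'
#' Negates X coordinates and flips face winding so outward orientation is
#' preserved. Applying it twice returns the original mesh.
#'
#' @param mesh a `bone_mesh`.
#' @return The mirrored `bone_mesh`; annotation points are mirrored too.
#' @export
mirror_mesh <- function(mesh) {
  out <- mesh
  out$vertices[, 1] <- -out$vertices[, 1]
  out$faces <- out$faces[, c(1, 3, 2)]
  if (!is.null(out$head_center)) out$head_center[1] <- -out$head_center[1]
  out$side <- if (identical(mesh$side, "right")) "left" else if (identical(mesh$side, "left")) "right" else mesh$side
  out
}

#' Read and write meshes as ASCII PLY or OBJ
#'
#' Plain-text I/O for interchange with standard mesh tools. `write_ply()` and
#' `write_obj()` store vertices and triangular faces only; annotations are not
#' persisted.
#'
#' @param mesh a `bone_mesh`.
#' @param path file path.
#' @return `read_ply()`/`read_obj()` return a `bone_mesh`; the writers return
#'   `path` invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  header <- c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(v)),
    "property double x", "property double y", "property double z",
    paste("element face", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  vl <- sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3])
  fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(header, vl, fl), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not an ascii PLY file: ", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  vl <- lines[(end + 1):(end + nv)]
  fl <- lines[(end + nv + 1):(end + nv + nf)]
  v <- matrix(scan(text = vl, quiet = TRUE), ncol = 3, byrow = TRUE)
  fraw <- matrix(scan(text = fl, quiet = TRUE), ncol = 4, byrow = TRUE)
  bone_mesh(v, fraw[, 2:4] + 1L)
}

#' @rdname write_ply
#' @export
write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(
    sprintf("v %.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]),
    sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
  ), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  v <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE), ncol = 3, byrow = TRUE)
  f <- matrix(scan(text = sub("^f ", "", fl), quiet = TRUE), ncol = 3, byrow = TRUE)
  bone_mesh(v, f)
}
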