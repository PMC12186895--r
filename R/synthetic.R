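#' Specify a specimen group
#'
#' A group is a distribution over [bone_params()]: per-field means and
#' standard deviations plus a posture label. Groups emulate the structure of a
#' comparative sample in which postural classes occupy distinct regions of
#' morphospace.
#'
#' @param name group label.
#' @param param_means a [bone_params()] object of field means.
#' @param param_sds named list/vector of per-field standard deviations
#'   (fields omitted default to 0; all must be >= 0).
#' @param posture `"sprawling"`, `"parasagittal"` or `"unknown"`.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(name, param_means = bone_params(), param_sds = list(),
                       posture = c("sprawling", "parasagittal", "unknown")) {
  posture <- match.arg(posture)
  numeric_fields <- setdiff(names(param_means), "side")
  sds <- setNames(rep(0, length(numeric_fields)), numeric_fields)
  if (length(param_sds)) {
    bad <- setdiff(names(param_sds), numeric_fields)
    if (length(bad)) stop("unknown parameter fields in param_sds: ", paste(bad, collapse = ", "))
    sds[names(param_sds)] <- unlist(param_sds)
  }
  if (any(sds < 0)) stop("param_sds must be >= 0")
  structure(list(name = name, param_means = param_means, param_sds = sds,
                 posture = posture),
            class = "group_spec")
}

# per-field truncation bounds that keep bone_params valid
param_bounds <- function(field) {
  switch(field,
    length = c(1e-6, Inf),
    shaft_radius_x = c(1e-6, Inf),
    shaft_radius_y = c(1e-6, Inf),
    proximal_flare = c(1, Inf),
    distal_flare = c(1, Inf),
    torsion_deg = c(0, 180 - 1e-9),
    curvature = c(-Inf, Inf),
    crest_height_frac = c(1e-6, 1 - 1e-6),
    crest_azimuth_deg = c(-Inf, Inf),
    crest_amplitude = c(0, Inf),
    head_radius = c(1e-6, Inf),
    c(-Inf, Inf)
  )
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (k in 1:1000) {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- min(max(v, lo), hi)
  }
  out
}

#' Draw bone parameters for a group
#'
#' Each numeric field is drawn independently from a normal distribution
#' truncated to the field's validity range; the head radius is additionally
#' kept below half the drawn length.
#'
#' @param spec a [group_spec()].
#' @param n number of parameter sets (>= 1).
#' @param seed integer RNG seed.
#' @return A list of `n` [bone_params()] objects.
#' @export
sample_group <- function(spec, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  fields <- names(spec$param_sds)
  draws <- lapply(fields, function(f) {
    b <- param_bounds(f)
    rnorm_trunc(n, spec$param_means[[f]], spec$param_sds[[f]], b[1], b[2])
  })
  names(draws) <- fields
  lapply(seq_len(n), function(i) {
    p <- lapply(draws, `[[`, i)
    p$head_radius <- min(p$head_radius, 0.45 * p$length)
    p$side <- spec$param_means$side
    do.call(bone_params, p)
  })
}

#' Default study groups
#'
#' Four synthetic groups emulating the comparative structure of a
#' sprawling-to-parasagittal sample: gracile high-torsion "herptile"-like
#' sprawlers, robust high-torsion "monotreme"-like sprawlers, gracile
#' low-torsion "therian"-like parasagittal forms, and an intermediate fossil
#' group of unknown posture.
#'
#' @return Named list of [group_spec()] objects.
#' @export
default_groups <- function() {
  sds <- list(length = 0.5, shaft_radius_x = 0.05, shaft_radius_y = 0.04,
              proximal_flare = 0.05, distal_flare = 0.05, torsion_deg = 5,
              curvature = 0.004, crest_height_frac = 0.02,
              crest_azimuth_deg = 6, crest_amplitude = 0.06, head_radius = 0.06)
  list(
    herptile = group_spec(
      "herptile",
      bone_params(length = 11.5, shaft_radius_x = 0.75, shaft_radius_y = 0.5,
                  torsion_deg = 45, crest_amplitude = 0.45, head_radius = 1.0,
                  proximal_flare = 1.25, distal_flare = 1.45),
      sds, posture = "sprawling"
    ),
    monotreme = group_spec(
      "monotreme",
      bone_params(length = 8.5, shaft_radius_x = 1.15, shaft_radius_y = 0.8,
                  torsion_deg = 35, crest_amplitude = 0.65, head_radius = 1.35,
                  proximal_flare = 1.5, distal_flare = 1.7),
      sds, posture = "sprawling"
    ),
    therian = group_spec(
      "therian",
      bone_params(length = 12, shaft_radius_x = 0.7, shaft_radius_y = 0.55,
                  torsion_deg = 8, crest_amplitude = 0.35, head_radius = 1.15,
                  proximal_flare = 1.2, distal_flare = 1.3),
      sds, posture = "parasagittal"
    ),
    fossil = group_spec(
      "fossil",
      bone_params(length = 10, shaft_radius_x = 0.9, shaft_radius_y = 0.62,
                  torsion_deg = 25, crest_amplitude = 0.5, head_radius = 1.2,
                  proximal_flare = 1.35, distal_flare = 1.5),
      sds, posture = "unknown"
    )
  )
}

#' Generate a synthetic specimen set
#'
#' Samples bone parameters per group, builds the meshes, and (optionally)
#' simulates a pure-birth phylogeny whose tips are the specimen ids, assigned
#' so that groups form contiguous blocks of the tree's tip sequence.
#'
#' @param groups list of [group_spec()] objects (>= 2 for downstream bgPCA).
#' @param n_per_group specimens per group.
#' @param with_tree attach a simulated phylogeny.
#' @param seed integer RNG seed.
#' @param n_axial,n_radial mesh resolution passed to [make_bone()].
#' @return An object of class `specimen_set`: a list with `specimens` (tibble
#'   with id, group, posture, side, list-columns `params` and `mesh`) and
#'   `tree` (a `phylo` or `NULL`).
#' @export
make_dataset <- function(groups, n_per_group = 8, with_tree = FALSE, seed = 1L,
                         n_axial = 48, n_radial = 48) {
  if (length(groups) < 2) stop("need >= 2 groups for downstream ordination")
  rows <- purrr::imap(groups, function(g, key) {
    gseed <- seed + 1000L * match(key, names(groups) %||% seq_along(groups))
    params <- sample_group(g, n_per_group, seed = gseed)
    tibble::tibble(
      id = sprintf("%s_%02d", g$name, seq_len(n_per_group)),
      group = g$name,
      posture = g$posture,
      side = vapply(params, `[[`, "", "side"),
      params = params
    )
  })
  specimens <- dplyr::bind_rows(rows)
  if (anyDuplicated(specimens$id)) stop("specimen ids must be unique")
  specimens$mesh <- purrr::map(specimens$params, make_bone,
                               n_axial = n_axial, n_radial = n_radial)
  tree <- NULL
  if (with_tree) {
    tree <- simulate_tree(nrow(specimens), birth_rate = 1, death_rate = 0,
                          seed = seed + 77L)
    # assign ids along the plotted tip sequence so groups are clade-like
    ord <- tip_sequence(tree)
    tree$tip.label[ord] <- specimens$id
  }
  structure(list(specimens = specimens, tree = tree), class = "specimen_set")
}

# tips in the order encountered by a depth-first traversal
tip_sequence <- function(tree) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  ord <- rev(postorder_edges(tree)) # preorder
  seq_tips <- integer(0)
  for (e in ord) if (edge[e, 2] <= n) seq_tips <- c(seq_tips, edge[e, 2])
  seq_tips
}

#' @export
print.specimen_set <- function(x, ...) {
  cat(sprintf("<specimen_set: %d specimens, %d groups%s>\n",
              nrow(x$specimens), length(unique(x$specimens$group)),
              if (is.null(x$tree)) "" else ", with tree"))
  print(dplyr::count(x$specimens, .data$group, .data$posture))
  invisible(x)
}

#' Write a specimen set to disk
#'
#' Meshes as ASCII PLY, metadata (id, group, posture, side and ground-truth
#' parameters) as CSV, and the tree (if any) as Newick.
#'
#' @param set a `specimen_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_specimen_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- dplyr::select(set$specimens, "id", "group", "posture", "side")
  pj <- purrr::map_dfr(set$specimens$params, function(p) {
    tibble::as_tibble(p[setdiff(names(p), "side")])
  })
  utils::write.csv(dplyr::bind_cols(meta, pj),
                   file.path(dir, "specimens.csv"), row.names = FALSE)
  purrr::walk2(set$specimens$mesh, set$specimens$id, function(m, id) {
    write_ply(m, file.path(dir, paste0(id, ".ply")))
  })
  if (!is.null(set$tree)) {
    writeLines(write_newick(set$tree), file.path(dir, "tree.nwk"))
  }
  invisible(dir)
}
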