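#' Demo pipeline configuration
#'
#' A small but complete configuration for [run_pipeline()]: the four default
#' study groups, a simulated phylogeny, the full landmark protocol
#' (21 x 24), and the standard landscape settings (0.05 weight increment,
#' top-10% averaging, AIC shift threshold 4). Values can be overridden by
#' name.
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   replaced wholesale).
#' @return A named list of class `pipeline_config`.
#' @export
demo_config <- function(...) {
  cfg <- list(
    seed = 1L,
    synthetic = list(n_per_group = 6, n_axial = 40, n_radial = 36,
                     with_tree = TRUE),
    slicing = list(n_slices = 21, n_per_slice = 24, span = c(0.01, 0.99)),
    grid = list(n_x = 60, n_y = 60, pad_frac = 0.05),
    variogram = list(model = "spherical", nugget = 0),
    weights = list(increment = 0.05, top_fraction = 0.10),
    sprawling_groups = NULL,   # default: groups labelled sprawling
    parasagittal_group = NULL, # default: the group labelled parasagittal
    models = c("BM1", "BMtrend", "OU1"),
    delta_aic = 4,
    shift_search = FALSE,
    write_meshes = FALSE,
    n_perm = 499
  )
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [demo_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  do.call(demo_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic specimen generation, slice landmarking,
#' Procrustes alignment and bgPCA ordination, trait measurement, kriged
#' performance surfaces, group adaptive landscapes, the transitional
#' sprawling-parasagittal landscape and taxon scores, Pareto landscapes along
#' the phylogenetic backbone, and evolutionary model comparison on the
#' transitional scores. All outputs are written under `out_dir` and recorded
#' (with md5 checksums) in `manifest.json`; reruns with the same config and
#' seed are bit-identical.
#'
#' @param config a `pipeline_config` (see [demo_config()], [read_config()]).
#' @param out_dir output directory.
#' @param groups optional named list of [group_spec()]; defaults to
#'   [default_groups()].
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the main in-memory objects and the manifest.
#' @export
run_pipeline <- function(config = demo_config(), out_dir, groups = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"), "] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  keep <- function(p) { paths[[length(paths) + 1]] <<- p; p }
  seed <- as.integer(config$seed)

  say("stage 1/8: synthetic specimens")
  groups <- groups %||% default_groups()
  set <- make_dataset(groups,
                      n_per_group = config$synthetic$n_per_group,
                      with_tree = isTRUE(config$synthetic$with_tree),
                      seed = seed,
                      n_axial = config$synthetic$n_axial,
                      n_radial = config$synthetic$n_radial)
  meta <- dplyr::select(set$specimens, "id", "group", "posture", "side")
  utils::write.csv(as.data.frame(meta), keep(file.path(out_dir, "specimens.csv")),
                   row.names = FALSE)
  if (isTRUE(config$write_meshes)) {
    mdir <- file.path(out_dir, "meshes")
    dir.create(mdir, showWarnings = FALSE)
    purrr::walk2(set$specimens$mesh, set$specimens$id,
                 function(m, id) keep(write_ply(m, file.path(mdir, paste0(id, ".ply")))))
  }
  if (!is.null(set$tree)) {
    writeLines(write_newick(set$tree), keep(file.path(out_dir, "tree.nwk")))
  }

  say("stage 2/8: landmarking")
  sl <- config$slicing
  landmarks <- purrr::map2_dfr(set$specimens$mesh, set$specimens$id, function(m, id) {
    landmark_bone(m, n_slices = sl$n_slices, n_per_slice = sl$n_per_slice,
                  span = sl$span, specimen_id = id)
  })
  write_landmarks_csv(landmarks, keep(file.path(out_dir, "landmarks.csv")))

  say("stage 3/8: GPA + bgPCA morphospace")
  proc <- gpa(landmarks)
  ms <- bgpca(proc, set$specimens$posture)
  scores <- ms$scores |>
    dplyr::select(-"group") |>
    dplyr::left_join(meta, by = c(specimen = "id")) |>
    dplyr::mutate(centroid_size = unname(proc$centroid_sizes[.data$specimen]))
  utils::write.csv(as.data.frame(scores),
                   keep(file.path(out_dir, "morphospace_scores.csv")), row.names = FALSE)
  perm <- permutation_group_test(ms$all_scores, set$specimens$posture,
                                 n_perm = config$n_perm, seed = seed + 3L)

  say("stage 4/8: functional traits")
  traits <- build_trait_table(set, n_slices = sl$n_slices,
                              n_per_slice = sl$n_per_slice, span = sl$span)
  write_trait_table(traits, keep(file.path(out_dir, "trait_table.csv")))

  say("stage 5/8: kriged performance surfaces")
  grid <- grid_spec(ms, n_x = config$grid$n_x, n_y = config$grid$n_y,
                    pad_frac = config$grid$pad_frac)
  surfaces <- trait_surfaces(traits, ms, grid = grid,
                             model = config$variogram$model,
                             nugget = config$variogram$nugget)
  sdir <- file.path(out_dir, "surfaces")
  dir.create(sdir, showWarnings = FALSE)
  purrr::iwalk(surfaces, function(s, nm) {
    keep(write_grid_csv(s, file.path(sdir, paste0(nm, ".csv"))))
  })

  say("stage 6/8: adaptive landscapes (weight enumeration)")
  W <- enumerate_weights(length(surfaces), config$weights$increment)
  glabs <- unique(set$specimens$group)
  land <- lapply(glabs, function(g) {
    gx <- scores[scores$group == g, c("axis1", "axis2")]
    group_landscape(surfaces, gx, weights = W,
                    top_fraction = config$weights$top_fraction)
  })
  names(land) <- glabs
  ldir <- file.path(out_dir, "landscapes")
  dir.create(ldir, showWarnings = FALSE)
  purrr::iwalk(land, function(l, nm) {
    keep(write_grid_csv(l, file.path(ldir, paste0(nm, ".csv"))))
  })
  wtab <- purrr::imap_dfr(land, function(l, nm) {
    tibble::tibble(group = nm, trait = names(l$weights), weight = unname(l$weights))
  })
  utils::write.csv(as.data.frame(wtab), keep(file.path(out_dir, "landscape_weights.csv")),
                   row.names = FALSE)

  say("stage 7/8: transitional + Pareto landscapes")
  post <- dplyr::distinct(set$specimens, .data$group, .data$posture)
  spr <- config$sprawling_groups %||% post$group[post$posture == "sprawling"]
  par <- config$parasagittal_group %||% post$group[post$posture == "parasagittal"][1]
  trans <- transitional_landscape(composite_max(land[spr]), land[[par]])
  keep(write_grid_csv(trans, file.path(out_dir, "transitional.csv")))
  tscores <- score_taxa(trans, dplyr::rename(scores, taxon = "specimen"))
  utils::write.csv(as.data.frame(tscores),
                   keep(file.path(out_dir, "transitional_scores.csv")), row.names = FALSE)

  pareto <- NULL
  nodeland <- NULL
  if (!is.null(set$tree)) {
    tree <- set$tree
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    derived_tips <- set$specimens$id[set$specimens$group == par]
    derived_node <- ape::getMRCA(tree, derived_tips)
    segment <- as.character(c(root, derived_node))
    nodeland <- node_landscapes(tree, ms, surfaces, weights = W,
                                nodes = c(root, derived_node),
                                top_fraction = config$weights$top_fraction)
    pareto <- pareto_for_segment(tree, nodeland, segment,
                                 dplyr::rename(scores, taxon = "specimen"))
    keep(write_grid_csv(pareto$landscape,
                        file.path(out_dir, sprintf("pareto_%s_%s.csv", segment[1], segment[2]))))
    utils::write.csv(as.data.frame(pareto$taxon_scores),
                     keep(file.path(out_dir, "pareto_scores.csv")), row.names = FALSE)
  }

  say("stage 8/8: evolutionary model comparison")
  models_tb <- NULL
  shift <- NULL
  if (!is.null(set$tree)) {
    x <- stats::setNames(tscores$score, tscores$taxon)
    fits <- lapply(config$models, function(mn) fit_model(set$tree, x, mn))
    models_tb <- compare_models(fits)
    utils::write.csv(as.data.frame(models_tb),
                     keep(file.path(out_dir, "evo_models.csv")), row.names = FALSE)
    if (isTRUE(config$shift_search)) {
      shift <- forward_shift_search(set$tree, x, delta_aic = config$delta_aic)
      utils::write.csv(as.data.frame(shift$trail),
                       keep(file.path(out_dir, "shift_trail.csv")), row.names = FALSE)
    }
  }

  manifest <- list(
    config = config[setdiff(names(config), "groups")],
    seed = seed,
    r_version = as.character(getRversion()),
    permutation_test = perm,
    files = lapply(paths, function(p) {
      list(path = sub(paste0("^", out_dir, "/?"), "", p),
           md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", length(paths), " artifacts in ", out_dir)
  invisible(list(
    set = set, landmarks = landmarks, proc = proc, morphospace = ms,
    traits = traits, surfaces = surfaces, landscapes = land,
    transitional = trans, transitional_scores = tscores,
    node_landscapes = nodeland, pareto = pareto, models = models_tb,
    shift = shift, manifest = manifest, paths = paths
  ))
}
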