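#' Per-cell maximum of several landscapes
#'
#' Overlays adaptive landscapes sharing one grid and keeps the highest value
#' in each cell — used to build the composite sprawling landscape from the
#' individual sprawling-group landscapes.
#'
#' @param landscapes list of `adaptive_landscape` (>= 1) on identical grids.
#' @return An `adaptive_landscape` whose `values` are the cellwise maxima
#'   (`weights`/`focal` are those of the contributing inputs, as a list).
#' @export
composite_max <- function(landscapes) {
  if (!length(landscapes)) stop("need >= 1 landscape")
  g <- landscapes[[1]]$grid
  for (l in landscapes) {
    if (!same_grid(l$grid, g)) stop("landscapes are on different grids")
  }
  vals <- Reduce(pmax, lapply(landscapes, `[[`, "values"))
  structure(
    list(grid = g, values = vals,
         weights = lapply(landscapes, `[[`, "weights"),
         focal = lapply(landscapes, `[[`, "focal"),
         sources = names(landscapes)),
    class = "adaptive_landscape"
  )
}

#' Transitional sprawling-parasagittal landscape
#'
#' Per-cell difference `parasagittal - sprawling`: negative cells perform
#' better on the composite sprawling landscape, positive cells on the
#' parasagittal (therian) landscape.
#'
#' @param sprawling_composite,parasagittal `adaptive_landscape`s on one grid.
#' @return An object of class `transitional_landscape` (`grid`, signed
#'   `values`, source labels).
#' @export
transitional_landscape <- function(sprawling_composite, parasagittal) {
  if (!same_grid(sprawling_composite$grid, parasagittal$grid)) {
    stop("landscapes are on different grids")
  }
  structure(
    list(grid = parasagittal$grid,
         values = parasagittal$values - sprawling_composite$values,
         source_sprawling = sprawling_composite$sources %||% "sprawling",
         source_parasagittal = "parasagittal"),
    class = "transitional_landscape"
  )
}

#' Score taxa on a gridded landscape
#'
#' Bilinear interpolation of the landscape height at each taxon's morphospace
#' position (nearest-cell lookup available as an option).
#'
#' @param landscape any gridded landscape object (`values` field).
#' @param points tibble/data frame with columns `taxon` (or `specimen`),
#'   `axis1`/`x`, `axis2`/`y`, or a plain two-column matrix.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return A tibble `taxon`, `score`.
#' @export
score_taxa <- function(landscape, points, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (is.data.frame(points)) {
    taxa <- points$taxon %||% points$specimen %||% rownames(points) %||%
      as.character(seq_len(nrow(points)))
    xy <- as.matrix(points[, intersect(c("axis1", "axis2", "x", "y"), names(points))[1:2]])
  } else {
    xy <- as.matrix(points)
    taxa <- rownames(xy) %||% as.character(seq_len(nrow(xy)))
  }
  vals <- landscape$values %||% landscape$score
  g <- landscape$grid
  score <- if (method == "bilinear") {
    interp_bilinear(g, vals, xy, labels = taxa)
  } else {
    ix <- vapply(xy[, 1], function(v) which.min(abs(g$x - v)), 0L)
    iy <- vapply(xy[, 2], function(v) which.min(abs(g$y - v)), 0L)
    vals[cbind(ix, iy)]
  }
  tibble::tibble(taxon = taxa, score = unname(score))
}

#' Pareto ranks of grid cells under two objectives
#'
#' Iterative non-dominated sorting, maximising both objectives: cell u
#' dominates v iff u >= v on both and > on at least one; cells tied on both
#' objectives share a front. The optimal ranking `R_O` peels non-dominated
#' fronts from the top; the suboptimal ranking `R_S` does the same with both
#' objectives negated. Implemented by a sorted staircase sweep
#' (O(n log n)); the brute-force O(n^2) dominance oracle used in the tests is
#' available as `pareto_ranks_bruteforce()`.
#'
#' @param values_a,values_b numeric matrices/vectors of identical shape
#'   (heights on the two landscapes).
#' @return A list with integer `R_O` and `R_S` of the input shape.
#' @export
pareto_ranks <- function(values_a, values_b) {
  if (!identical(dim(values_a), dim(values_b)) ||
      length(values_a) != length(values_b)) {
    stop("objective grids differ in shape")
  }
  ro <- nds_front_ranks(as.vector(values_a), as.vector(values_b))
  rs <- nds_front_ranks(-as.vector(values_a), -as.vector(values_b))
  if (!is.null(dim(values_a))) {
    ro <- array(ro, dim(values_a))
    rs <- array(rs, dim(values_a))
  }
  list(R_O = ro, R_S = rs)
}

# front index per point for 2-objective maximization
nds_front_ranks <- function(a, b) {
  # %.17g keys are exact for doubles: only true ties collapse
  key <- paste(sprintf("%.17g", a), sprintf("%.17g", b))
  uniq <- !duplicated(key)
  ua <- a[uniq]; ub <- b[uniq]
  ord <- order(ua, ub, decreasing = TRUE)
  front <- integer(length(ua))
  maxb <- numeric(0) # per-front max of b among processed points (non-increasing)
  for (i in ord) {
    bi <- ub[i]
    # first front whose max-b is below bi -> not dominated there
    lo <- 1L; hi <- length(maxb) + 1L
    while (lo < hi) { # binary search on the non-increasing maxb
      mid <- (lo + hi) %/% 2L
      if (maxb[mid] >= bi) lo <- mid + 1L else hi <- mid
    }
    front[i] <- lo
    if (lo > length(maxb)) maxb <- c(maxb, bi) else maxb[lo] <- max(maxb[lo], bi)
  }
  front[match(key, key[uniq])]
}

#' @rdname pareto_ranks
#' @export
pareto_ranks_bruteforce <- function(values_a, values_b) {
  a <- as.vector(values_a); b <- as.vector(values_b)
  rank_one <- function(a, b) {
    n <- length(a)
    rk <- integer(n)
    left <- seq_len(n)
    r <- 1L
    while (length(left)) {
      nd <- vapply(left, function(i) {
        !any((a[left] >= a[i] & b[left] >= b[i]) &
               (a[left] > a[i] | b[left] > b[i]))
      }, TRUE)
      rk[left[nd]] <- r
      left <- left[!nd]
      r <- r + 1L
    }
    rk
  }
  ro <- rank_one(a, b)
  rs <- rank_one(-a, -b)
  if (!is.null(dim(values_a))) {
    ro <- array(ro, dim(values_a)); rs <- array(rs, dim(values_a))
  }
  list(R_O = ro, R_S = rs)
}

#' Pareto optimality score from the two rankings
#'
#' `score = (R_S - 1) / (R_O + R_S - 2)`, a linear 0-1 rank where 1 marks the
#' Pareto-optimal front and 0 the most suboptimal cells. Cells with
#' `R_O = R_S = 1` (degenerate denominator) are scored 1: they lie on the
#' first non-dominated front, which takes precedence.
#'
#' @param R_O,R_S integer rank grids from [pareto_ranks()].
#' @return Numeric grid of scores in \[0, 1\].
#' @export
pareto_score <- function(R_O, R_S) {
  den <- R_O + R_S - 2
  out <- ifelse(den == 0, 1, (R_S - 1) / pmax(den, 1L))
  if (!is.null(dim(R_O))) out <- array(out, dim(R_O))
  out
}

#' Pareto landscape from two adaptive landscapes
#'
#' @param ancestral,derived `adaptive_landscape`s on one grid (the two
#'   objectives).
#' @return An object of class `pareto_landscape`: `grid`, `R_O`, `R_S`,
#'   `score`.
#' @export
pareto_landscape <- function(ancestral, derived) {
  if (!same_grid(ancestral$grid, derived$grid)) stop("landscapes are on different grids")
  rk <- pareto_ranks(ancestral$values, derived$values)
  structure(
    list(grid = ancestral$grid, R_O = rk$R_O, R_S = rk$R_S,
         score = pareto_score(rk$R_O, rk$R_S)),
    class = "pareto_landscape"
  )
}

#' Pareto optimality along a phylogenetic segment
#'
#' Builds the Pareto landscape for an (ancestral node, derived node) pair of
#' reconstructed adaptive landscapes, scores each taxon's position on it, and
#' optionally reconstructs ancestral states of the scores under Brownian
#' motion.
#'
#' @param tree a `phylo` object.
#' @param node_landscapes result of [node_landscapes()].
#' @param segment length-2 vector naming the ancestral and derived nodes
#'   (names of `node_landscapes` entries).
#' @param taxon_points tibble `taxon`/`specimen`, `axis1`, `axis2`.
#' @param asr reconstruct ancestral score states.
#' @return A list: `landscape` (`pareto_landscape`), `taxon_scores` tibble,
#'   `node_states` (named vector or `NULL`).
#' @export
pareto_for_segment <- function(tree, node_landscapes, segment, taxon_points,
                               asr = TRUE) {
  seg <- as.character(segment)
  if (!all(seg %in% names(node_landscapes))) {
    stop("segment nodes not found among the node landscapes")
  }
  pl <- pareto_landscape(node_landscapes[[seg[1]]]$landscape,
                         node_landscapes[[seg[2]]]$landscape)
  scores <- score_taxa(pl, taxon_points)
  node_states <- NULL
  if (asr) {
    x <- stats::setNames(scores$score, scores$taxon)
    node_states <- asr_bm(tree, x)
  }
  list(landscape = pl, taxon_scores = scores, node_states = node_states)
}
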