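---
title: "Adaptive-landscape analysis of long-bone form and function: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-landscape analysis of long-bone form and function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humeroscape)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter, what the synthetic
data generator does and does not emulate, and the numerical and design
choices made where the method leaves them open.

## The scientific problem

The transition from sprawling to parasagittal (upright) limb posture is a
central event in the evolution of mammals from their non-mammalian synapsid
forebears. The humerus is a useful lens on that transition: it anchors the
main locomotor muscles, articulates the forelimb with the body, and
fossilises well. The analytical framework implemented here links humerus
*shape* (a morphospace built from surface landmarks) to humerus *function*
(seven osteological performance proxies) through adaptive landscapes:
weighted sums of performance surfaces in which the weights are chosen to
maximise the performance of a focal shape. Differences in the optimal
weightings between postural groups, the signed difference between sprawling
and parasagittal landscapes, and Pareto optimality between successive
ancestral landscapes together characterise how posture could evolve through
morphospace.

## Synthetic specimens

Real analyses of this kind start from digitised bones. The package instead
generates parametric bones with *known* ground truth, so that every
downstream measurement has an analytic target. A bone is an
elliptical-section shaft along global Z (distal pole at z = 0), with:

* end flares (`proximal_flare`, `distal_flare` ≥ 1), ramped smoothly over
  the outer ~12–15% of the shaft so the mid-shaft window used for crest
  detection is unaffected;
* a linear twist of the section's major axis — humeral torsion — rising
  from 0 at the distal end to `torsion_deg` at the base of the head. The
  twist deliberately stops there: sections through the hemispherical head
  cap are circles, whose principal axes are undefined, so carrying the
  twist into the cap would make the end-contour torsion measurement
  meaningless. Correspondingly, the trait table measures torsion on the
  sub-head (diaphyseal) contours;
* a gentle sagittal bow (`curvature`, default 2% of length), frozen at its
  head-base value above the shaft so the articular cap remains an exact
  sphere;
* a Gaussian radial bump standing in for the deltopectoral crest
  (angular s.d. 0.5 rad, axial s.d. 6% of length), whose apex vertex is
  recorded — on real bones this point is identified manually, on synthetic
  ones the bump makes it unambiguous;
* a hemispherical articular head with stored centre and radius, giving the
  sphere-fit centre of rotation an analytic truth.

Groups are distributions over these parameters (independent truncated
normals per field). The four default groups emulate the comparative
structure of a posture study — gracile high-torsion sprawlers
("herptile"-like, torsion 45°), robust high-torsion sprawlers
("monotreme"-like, torsion 35°, strong crest and flares), gracile
low-torsion parasagittal forms ("therian"-like, torsion 8°), and an
intermediate fossil group of unknown posture (torsion 25°). The standard
deviations (e.g. 5° of torsion, ~5% of the linear dimensions) are chosen to
give clearly separated but internally variable groups, the regime a
comparative sample of this kind presents.

What the generator does **not** emulate: real anatomical detail (fossae,
condyle shape), cortical/internal geometry (the method assumes solid bones
anyway), measurement noise from photogrammetry, and taxon/specimen
distinctions (every specimen is an independent phylogeny tip). Passing
ground-truth tests therefore demonstrates that the *measurement and
landscape machinery* is correct, not that the biological inferences from any
real dataset would be.

## Landmarking and cross-sections

Each aligned bone is sliced at 21 stations evenly spaced over [1%, 99%] of
its Z extent. The endpoints are excluded because true end planes meet the
mesh in degenerate point contacts; the span is configurable, and the
protocol's landmark count (21 × 24 = 504) is asserted at the pipeline
boundary. Plane–mesh intersections are computed once per unique mesh edge
and chained by integer edge keys, so contours close exactly; if a plane
yields several loops (e.g. through head and crest simultaneously) the
largest-area loop is kept, as slice-based long-bone protocols do. Contours
are oriented counterclockwise viewed from +Z, and 24 landmarks are placed
equidistantly by arc length starting where the +X ray from the contour's
area centroid crosses the outline (the outermost crossing on non-convex
contours). This fixed start ray gives cross-specimen correspondence via the
shared anatomical alignment; no semilandmark sliding is performed because
the placement is already deterministic.

Cross-sectional area, centroid, and centroidal second moments of area are
computed with exact Green's-theorem polygon formulas, treating the section
as solid; `J = I_x + I_y` holds by construction. Analytic shapes (disc,
rectangle) validate these to their discretisation error.

## Functional traits

The seven traits, all dimensionless and invariant to isotropic scaling and
rigid motion by construction:

| trait | definition | default provenance of inputs |
|---|---|---|
| length | functional length / centroid size | max-Z and min-Z vertices |
| gyration | length / \|COM − COR\| | solid-mesh centroid; sphere fit to head vertices |
| torsion | sin(angle between end-contour major principal axes), angle in [0°, 180°) | sub-head slice contours |
| swing_force | mean of X- and Y-axis lever / length | crest apex, COR |
| swing_speed | mean of the *inverses* of the per-axis force advantages | same |
| spin | Z-axis lever / centroid size | same |
| strength | (mean I_x over slices)^(1/4) / centroid size | all 21 slice sections |

Moment arms are perpendicular distances from the crest apex to the axis
lines through the centre of rotation — the mechanically meaningful reading
of decomposing an in-lever "about anatomical axes". The velocity advantage
is computed per axis and then averaged (the mean of inverses, not the
inverse of the mean); this ordering is asserted in the tests. Near-circular
end contours (principal-axis ratio < 1.05) make the torsion axis unstable;
the implementation warns and proceeds, and the generator avoids the
situation by keeping shaft sections elliptical (default axis ratio 1.5).
Each trait column is min–max scaled to [0, 1] across the sample; a constant
column is set to 0.5 with a warning rather than dropped, so the
seven-surface structure is preserved.

## Morphospace

Generalised Procrustes alignment centres each 504-landmark configuration,
scales it to unit centroid size, and iteratively rotates all configurations
onto the evolving mean (rotation-only — mirrored specimens are handled
upstream by explicit mesh mirroring) until the mean changes by less than
1e-10. Ordination is a between-groups PCA on the three posture labels
(sprawling / parasagittal / unknown): the axes are the principal components
of the equally weighted group-mean matrix, and every specimen is projected
onto them, giving at most (groups − 1) = 2 axes — the 2D morphospace used by
all landscapes. Plain PCA is retained for comparison. Group separation is
tested by a label-permutation test on the between-group fraction of the
score sum of squares; the full Procrustes-ANOVA machinery with
centroid-size covariates is out of scope, and the permutation test holds
its nominal type-I error in simulation.

## Performance surfaces: ordinary kriging

Each scaled trait is interpolated over a grid (default 100 × 100, the
specimen bounding box padded by 5%; the method itself states no resolution)
by ordinary kriging with a spherical semivariogram fitted by weighted least
squares (12 lag bins to half the maximum pair distance, weights N/h²). The
nugget defaults to zero, which makes the predictor an exact interpolator —
a property asserted at 1e-6 at every specimen. Duplicate specimen locations
would make the kriging system singular and are jittered by 1e-8 with a
warning; a flat (zero-sill) variogram receives a tiny ridge so prediction
degrades gracefully to the sample mean. Kriging is deliberately
assumption-light about the number of performance peaks, at the price of
rugose surfaces.

## Adaptive landscapes

Candidate trait weightings are *all* non-negative 7-vectors summing to 1 in
steps of 0.05 — the 230,230 compositions of 20 among 7 slots (the count
C(26, 6) itself confirms the simplex constraint). Every vector is scored by
the height it gives the focal point (surfaces bilinearly interpolated); the
top 10% (23,023 vectors, ties at the cutoff broken by the deterministic
enumeration order) are averaged component-wise and renormalised to sum to 1,
and the landscape is the weighted sum of the seven surfaces under those mean
weights. Group landscapes use the group's mean morphospace position as the
focal point by default (a mean-of-member-heights mode is provided);
ancestral-node landscapes place the focal point at per-axis maximum
likelihood Brownian ancestral states.

## Transitional and Pareto landscapes

The composite sprawling landscape is the per-cell maximum over the
individual sprawling-group landscapes (membership configurable); the
transitional landscape subtracts it from the parasagittal landscape, so
negative cells favour some mode of sprawling and positive cells the
parasagittal condition. Taxa are scored by bilinear interpolation (a
nearest-cell mode exists for grid-resolution checks).

Pareto optimality treats every grid cell as a solution under two objectives
— its heights on an ancestral-node and a descendant-node landscape. Fronts
are peeled iteratively: cell *u* dominates *v* iff *u* ≥ *v* on both
objectives and > on at least one; cells tied on both share a front (the
method does not define grid ties, so this is the package's rule). The
optimal ranking R_O and the reversed-objective suboptimal ranking R_S give
the score (R_S − 1)/(R_O + R_S − 2), a linear 0–1 rank with 1 on the first
non-dominated front and 0 at the most dominated cells. Cells with
R_O = R_S = 1 (possible for mutually incomparable extremes or fully tied
grids) are scored 1: they sit on the optimal front, which takes precedence.
The production ranking is an O(n log n) staircase sweep over cells sorted by
the first objective; an O(n²) brute-force dominance oracle ships alongside
it and the two are cross-checked on random landscape pairs in the tests.
One numerical subtlety: tie detection uses exact (17-significant-digit)
value keys, so floating-point near-ties are *not* collapsed — only true
ties share fronts.

## Phylogenetic comparative machinery

Univariate models on rooted trees with branch lengths: single-rate BM,
BM with trend, multi-rate BM, and single/multi-peak OU with regime paintings
on branches. Two independent likelihood routes are implemented and
cross-checked to 1e-8: a pruning recursion, and dense GLS on the
phylogenetic covariance matrix. For OU, the pruning route uses the exact
transformation y_i = x_i·e^(αT_i), under which the OU covariance becomes
tree-additive with branch lengths (e^(2αb) − e^(2αa))/(2α); regime mean
weights accumulate along root paths in the same transformed space.

Fitting profiles the location parameters (root state, optima, trend) by GLS
and the diffusion σ² in closed form at each value of the shape parameters,
leaving a 1-D optimisation over α (bounds [1e-8, 50/T], five deterministic
starts — OU profiles can be multimodal) or (k−1) relative rates for
multi-rate BM. On ultrametric trees the OU root-state design column is
exactly collinear with the regime columns, so the root state is pinned to
the root regime's optimum there and estimated freely otherwise; parameter
counts follow. AICc uses the tip count as sample size. Ancestral states
under BM are the joint-ML (GLS) solution of the branch-weighted harmonic
system, cross-checked against an independent implementation.

The forward shift search starts from single-peak OU and, at each step,
considers a new regime on every branch (painting the branch and its
subtree). Candidates are screened with α fixed at the current estimate
(optima and σ² profiled — two orders of magnitude faster, and immune during
screening to the degeneracy where a one-tip regime drags α upward to pin an
outlier tip); the single best candidate is then refit with free α, and it is
accepted only if its AIC beats the current model's by more than the
threshold (default 4). There is no backward or convergence-merging phase.
A known limitation follows: under best-of-all-branches selection at
ΔAIC = 4, null (single-peak) data still admit a spurious shift in a
substantial fraction of replicates — the forward-phase overfitting that
backward phases exist to prune — so accepted shifts on real data should be
read as candidate hypotheses, and strong planted shifts (which the search
recovers reliably) as the regime the procedure is calibrated for.
Tree-set reruns refit the model list across a set of trees (e.g. varying
time calibrations) to tabulate the distribution of Akaike weights.

## Pipeline, determinism, and problem sizes

`run_pipeline()` executes the stages in order, writes CSV/Newick/JSON
artifacts with md5 checksums into a manifest, and is bit-identical under a
fixed config and seed; the single seed is fanned out to stages by fixed
offsets so stage-level outputs are individually reproducible, and
downstream-only config changes provably leave upstream artifacts untouched.
The demo configuration uses 4 groups × 6 specimens at mesh resolution
40 × 36, a 60 × 60 grid, and the full 0.05 weight increment; the test suite
exercises the same code paths at slightly smaller sizes (3–4 specimens per
group, 30 × 30 grids, increment 0.1 where the enumeration itself is not the
point), and the calibration battery uses 100-tip trees for rate recovery and
24-tip trees with 50 replicates for the shift-search simulations — sizes at
which the Monte-Carlo targets are stable.

## Known limitations

* Solid-bone assumption throughout; no cortical geometry.
* Univariate evolutionary models only; multivariate OU on the 7-weight
  vectors is out of scope.
* No covariate-adjusted (allometry) permutation testing.
* bgPCA can exaggerate group separation when groups are many and specimens
  few; the plain-PCA comparison is retained for that reason.
* The forward-only shift search overfits on null data at small thresholds,
  as discussed above.
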