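Package: humeroscape
Title: Adaptive-Landscape Analysis of Long-Bone Form and Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying the evolution of limb posture from long-bone
    (humerus) morphology. Generates parametric synthetic bone meshes with known
    ground truth, places slice-based pseudo-landmarks (21 contours x 24 points),
    computes seven osteological performance traits (functional length, radius of
    gyration, torsion, swing force and speed leverage, spin leverage, bending
    strength), builds a between-groups PCA morphospace from Procrustes-aligned
    landmarks, interpolates performance surfaces by ordinary kriging, constructs
    adaptive landscapes by exhaustive simplex weight enumeration with top-fraction
    averaging, derives transitional sprawling-parasagittal landscapes and
    two-objective Pareto optimality landscapes, and fits Brownian-motion and
    Ornstein-Uhlenbeck models of trait evolution on time-calibrated phylogenies
    with AIC-thresholded forward shift searches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
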