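Package: footmorph
Title: Ontogenetic Allometry and Convergence of Salamander Foot Morphology
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric-morphometric and phylogenetic-comparative tools for
    studying how foot morphology changes during growth in plethodontid
    salamanders. Provides generalized Procrustes superimposition with
    Kendall tangent-space projection, thin-plate spline deformation grids,
    foot-webbing sinuosity, univariate and multivariate allometry models
    (ANCOVA, MANCOVA with Pillai's trace, shape regression scores), a
    permutation test of ontogenetic convergence based on summed pairwise
    distances among predicted juvenile and adult morphologies, two-state
    maximum-likelihood ancestral reconstruction of growth regime on a
    phylogeny, and allometric power-law fits of foot area against body
    weight. A calibrated synthetic-data generator emulating ontogenetic
    series of the eight European cave salamander species makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
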