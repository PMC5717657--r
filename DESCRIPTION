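Package: disparitree
Title: Disparity Through Time from Interpolated Shapes on Time-Scaled Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates morphological disparity through time by interpolating
    continuous shape variables along the branches of time-scaled phylogenies.
    Provides generalized Procrustes alignment of 2-D landmark configurations,
    principal component scores with broken-stick axis selection, stochastic
    'equal'-method time-scaling of supertrees with fossil tips under
    stratigraphic age uncertainty and node-age minimum constraints, ancestral
    state reconstruction under Brownian motion (equivalent to squared-change
    parsimony), per-bin sum-of-variances disparity curves with ensemble
    uncertainty bands across replicate trees, and correlation tests of
    disparity against environmental covariates (Spearman, OLS, and GLS with
    AR(1) errors). A synthetic-data module simulates birth-death trees with
    extinct tips, Brownian trait and landmark evolution, and stratigraphic
    ranges with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    nlme,
    e1071,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools,
    vegan,
    jsonlite
Config/testthat/edition: 3
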