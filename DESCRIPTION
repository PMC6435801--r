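Package: pmfdecomp
Title: Decomposition of Free-Energy Profiles Along a Folding Coordinate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes and decomposes potential-of-mean-force profiles of
    coarse-grained chain molecules along the end-to-end distance. Combines
    umbrella sampling with the weighted histogram analysis method (WHAM),
    a bidirectional dielectric-ladder free-energy-perturbation estimator of
    the excess chemical potential under a generalized Born / surface area
    continuum solvent, and exponential reweighting to a pluggable hydration
    free-energy backend. Assembles the thermodynamic cycle into
    intramolecular, solvent-induced, nonpolar and polar components, with
    temperature- and pressure-difference analyses, unfolding free energies
    and partial molar volume changes. Ships toy systems with closed-form
    profiles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
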