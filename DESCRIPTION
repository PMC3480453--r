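Package: antsym
Title: Individual-Based Simulation of Symmetry Breaking in Ant Trail Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time, individual-based simulation of an ant colony
    foraging at identical food patches connected to the nest by pheromone
    trails. Foragers pick a trail with a configurable decision rule (random
    null, linear, sigmoidal, or ranked choice), successful foragers lay
    pheromone on the way home, and trails evaporate each step. The package
    provides the trail-choice rules with a detection-threshold
    (discrimination) preprocessing step, a fast simulation engine with
    limited or unlimited patch capacity, a standardized asymmetry index for
    scoring how unevenly a colony exploits identical patches, replicated
    parameter sweeps returning tidy tables, and the statistical layer used
    to compare rules against the random-choice null model (quantile
    envelopes, rank-sum tests, asymmetry-versus-forager-number trends,
    threshold and divergence detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
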