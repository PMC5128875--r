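Package: fibrildmd
Title: Event-Driven Coarse-Grained Simulation and Polymorph Scoring of
    Amyloid Peptide Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discontinuous (event-driven) molecular dynamics for a
    four-sphere-per-residue coarse-grained peptide model with square-well
    interactions, directional backbone hydrogen bonding, an enhanced
    D23-K28 salt bridge and a parallel-preference bias, aimed at
    aggregation of the amyloid-beta 17-42 fragment.  Includes experiment
    orchestration (fixed-concentration box construction, constant and
    alternating temperature schedules), idealized fibril conformer
    generators (U-shape, S-shape serpentines, beta-helix, random coil),
    and a structure-analysis layer: chain-averaged intra-peptide C-alpha
    distance profiles, Pearson-correlation similarity against reference
    structures, fibril polymorph classification, in-register scoring,
    secondary-structure content, oligomer clustering and population heat
    maps.
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
    bio3d,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
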