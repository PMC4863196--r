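Package: cricketnets
Title: Social Networks of Pre- and Post-Copulatory Male Competition in
    Burrow-Dwelling Crickets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and analyses social networks of male-male competition
    in burrow-structured insect populations observed over a breeding
    season.  From tabular observation records (roster, burrow occupancy,
    fights, matings) it constructs a directed fighting network, a
    sperm-competition network as the weighted one-mode projection of the
    male-female mating network, and spatial and temporal overlap matrices;
    symmetrizes directed networks by the geometric mean of reciprocal edge
    weights; and tests within-pair association between fighting and sperm
    competition with multiple-regression quadratic assignment procedure
    (MRQAP) inference using Dekker double-semipartialling permutations.
    Node-level analyses cover degree and strength comparisons across
    networks and the degree correlation (assortativity by promiscuity) of
    the mating network against a spatially and temporally constrained
    edge-subsampling null model.  A configurable simulator of
    burrow-structured mating systems with plantable effects supports
    calibration and power studies of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr
Config/testthat/edition: 3
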