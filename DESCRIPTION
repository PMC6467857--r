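Package: lhigp
Title: Stage-Structured Bioenergetics of Life-History Intraguild Predation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ecological and eco-evolutionary analysis of a stage-structured
    biomass model of life-history intraguild predation, in which juvenile
    predators compete with a specialist consumer for a shared resource while
    adult predators prey on that consumer and, optionally, cannibalize
    juveniles.  Provides the bioenergetic rate functions and the four-species
    ordinary differential equations, stiff-capable simulation to attractors,
    direct equilibrium solving with Newton iteration, one-parameter branch
    continuation with fold and invasion-boundary detection, two-parameter
    stability maps, and adaptive-dynamics tools (invasion fitness as lifetime
    reproductive success, selection gradients, singular-strategy detection and
    classification, trait-substitution trajectories) for the ontogenetic
    trade-off between juvenile resource specialization and adult predation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
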