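Package: reciprobot
Title: Evolutionary Robotics Simulations of Helping and Reciprocity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An embodied foraging-and-helping simulation platform for studying
    the evolution of cooperation and reciprocity. Pairs of differential-drive
    robots controlled by feed-forward neural networks forage on a toroidal
    arena, become stuck stochastically, and can release one another; bitstring
    genotypes encoding the connection weights evolve under a Wright-Fisher
    process with controllable genetic relatedness and an optional memory
    neuron tracking past help received. The package provides standardized
    behavioral assays with maximum-likelihood helping-rate estimation under a
    censored-geometric model, artificial-selection breeding of reference
    strategies (Selfish, Helper, Reciprocator), Moran fixation-probability
    screening, and a game-dynamics layer for measured payoff matrices
    (game classification, invasion thresholds, finite-population
    three-strategy Wright-Fisher dynamics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
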