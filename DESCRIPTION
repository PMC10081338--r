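Package: dynmod
Title: Dynamical Modularity of Boolean Automata Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to decompose the dynamics of Boolean automata networks
    (gene regulatory and signalling models) into pathway modules. Node
    update rules are redescribed into wildcard and two-symbol schemata by
    Quine-McCluskey minimisation, assembled into a dynamics canalization
    map (DCM) threshold network, and unfolded from perturbed seed sets
    under pinning or pulse perturbation. The package classifies module
    interactions (subsumption, synergy, logical obstruction, decoupling),
    enumerates maximal, complex and core complex modules, and computes
    exact and greedy optimal covers of the DCM together with the mean
    dynamical modularity statistic and the characteristic seed number.
    Includes a rule-file parser, an exhaustive-simulation oracle, a
    lattice composition operator for multicellular models, and a seeded
    random-network generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
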