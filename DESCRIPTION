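Package: hbcube
Title: Combinatorial Genotype-Phenotype Analysis of Hemoglobin Function
Version: 0.1.0
Authors@R:
    person("Packaged", "Analysis", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for combinatorial analysis of protein
    genotype-phenotype landscapes, built around the functional
    characterization of hemoglobin variants. Fits Hill oxygen-equilibrium
    curves (P50, n50), monoexponential stopped-flow and autoxidation
    kinetics, and computes anion-sensitivity indices. Enumerates the
    genotype hypercube between an ancestral and a derived multi-site
    genotype, quantifies per-background mutation effects, mutational
    pathway trajectories, order dependence, reversion symmetry, and
    double-mutant-cycle epistasis. Polarizes amino-acid substitutions on
    a rooted species tree by parsimony, screens for pleiotropic
    trade-offs between traits, and ships a seeded synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
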