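Package: quasirep
Title: Spatial RNA Replicator Quasispecies Simulation and Mutational
    Neighborhood Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying eco-evolutionary dynamics of RNA-like
    replicators near the error threshold. Implements a dangling-end
    hybridization energy model, secondary-structure based functional
    phenotype classification (units of replication, parasites, helpers,
    stallers, junk, hybrids), a toroidal-grid Monte Carlo simulator of
    replicator populations with evolvable mutation rates and class
    knockout interventions, mutational-neighborhood (Hamming distance)
    spectrum analyses, an evolutionary optimizer for replication rate,
    and mass-action ODE models of replicator-parasite-helper/staller
    systems with equilibrium continuation and bifurcation detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
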