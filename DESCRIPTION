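Package: AMICoex
Title: Coexistence Analysis of Antibiotic-Mediated Microbial Interaction Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding which antibiotic-mediated interaction graphs
    allow stable coexistence of small microbial communities. Communities of N
    strains interacting through M antibiotics are represented as phenotype
    matrices over the symbols P (producer), S (sensitive), D (degrader) and R
    (intrinsically resistant). The package enumerates all unique communities
    up to strain and antibiotic relabelling, evolves relative abundances under
    a discrete-time replicator map with degrader-attenuated kill
    probabilities, locates fixed points and classifies their stability by the
    Jacobian spectral radius, classifies stable communities by PSD-motif
    coverage, cyclicity and extension structure, and runs individual-based
    stochastic simulations on a hexagonal lattice with quasi-static diffusion
    of antibiotic and degrader-enzyme fields.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
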