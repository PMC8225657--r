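Package: grnsim
Title: Simulation of Single Cells Driven by Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-modal single-cell simulation engine. A coarse module
    network is expanded into a gene regulatory network, single cells are
    simulated at single-molecule resolution with Gillespie's stochastic
    simulation algorithm under a thermodynamic model of transcriptional
    regulation, and single-cell sequencing experiments are emulated by
    sampling cells and molecules. Every dataset ships with its ground
    truths: the trajectory each cell occupies, the RNA velocity of every
    gene in every cell, and the cell-specific regulatory network. Includes
    the evaluation metrics needed to benchmark trajectory alignment, RNA
    velocity, and cell-specific network inference methods against those
    ground truths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    deSolve,
    tibble,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    SingleCellExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
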