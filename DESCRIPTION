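Package: qeqnet
Title: Graph Neural Network Charge Equilibration for Partial Atomic Charges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns partial atomic charges to molecules with a hybrid
    physical/machine-learning model: a message-passing graph neural network
    predicts per-atom electronegativity and hardness from resonance-independent
    topological features, and a closed-form charge-equilibration (QEq) step with
    a Lagrange-multiplier constraint converts them to charges that sum exactly
    to the total molecular charge, at cost linear in the number of atoms.
    Includes molecular graph construction and block-diagonal batching, training
    against reference charges with a squared loss, per-molecule RMSE evaluation
    with bootstrap confidence intervals and stratified summaries, a synthetic
    molecule/label generator for controlled experiments, SDF/MOL2 charge
    writers, and an antechamber-style command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    Matrix,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    generics,
    optparse,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
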