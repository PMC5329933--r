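Package: phenoDE
Title: Phenotype-Constrained Parameter Ensembles for Growth-Division Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates ensembles of kinetic parameter vectors for
    growth-division (cell cycle) dynamical models under discrete phenotype
    constraints. Parameter space is explored with Latin hypercube sampling
    and a modified differential evolution whose selection step enforces up
    to three feasibility criteria: phenotype capture, expansion of the
    feasible region's estimated volume, and novelty of the phenotypic
    prediction vector. The package computes prediction-range and
    sampling-efficiency statistics, perturbation-robustness scores,
    relative protein abundance variability statistics, and predicts the
    network module of a regulator from abundance statistics with a
    random forest evaluated by out-of-bag one-vs-rest ROC/AUC against a
    label-permutation null. A synthetic three-module growth-division toy
    model with a known feasible structure is included as a test fixture.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
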