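Package: fibrosim
Title: Hybrid Multi-Scale Agent-Based Simulation of a Fibroblast-Epithelial Co-Culture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid multi-scale model of an in vitro fibroblast-epithelial
    cell co-culture on a 3D voxel lattice. Soluble TGF-beta1 and PGE2 diffuse
    and decay in the media compartment; an intracellular receptor-trafficking
    ODE system runs inside every fibroblast and myofibroblast agent; cell
    agents move, proliferate, differentiate and die by probabilistic rules
    coupled to their local mediator concentrations. Includes dose-response
    calibration of the differentiation and apoptosis rules, Latin hypercube
    sampling with partial rank correlation (PRCC) sensitivity analysis, an
    outcome classifier for fibrotic versus healthy endpoints, and single
    versus combined ("two-hit") virtual treatment experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
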