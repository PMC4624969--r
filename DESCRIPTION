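Package: moranfield
Title: Spatial Moran Processes with Quenched Random Fitness and Cell Motility
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Stochastic death-birth Moran dynamics on square lattices in which
    every site carries its own quenched fitness value for residents and mutants,
    drawn from constant, uniform, triangular, bimodal or checkerboard
    distributions, optionally combined with fitness-independent cell motility.
    Provides a compiled update engine, Monte Carlo estimation of invasion
    (fixation) probabilities averaged over initial mutant placements and random
    fitness configurations, parameter sweeps, an exact absorbing-Markov-chain
    oracle for small lattices, closed-form well-mixed references, and a small
    command-line driver for reproducible seeded experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
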