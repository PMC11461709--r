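Package: abcgrow
Title: Calibration of Stochastic Agent-Based Neuron Growth Models with
    Approximate Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates three-dimensional neuron morphologies with
    resource-driven, agent-based growth rules (symmetric bifurcation and
    asymmetric side-branching models), reduces neurons to morphometric
    quantities of interest (segment counts and lengths), and calibrates the
    growth rules against observed morphologies with sequential Monte Carlo
    approximate Bayesian computation (SMC-ABC) driven by statistical
    distances between point clouds (exact Wasserstein, sliced Wasserstein,
    k-nearest-neighbour Kullback-Leibler and gamma divergences). Includes
    Saltelli sampling with Sobol sensitivity indices, posterior predictive
    checks, weighted kernel density summaries, SWC import/export, and a
    command-line interface for end-to-end workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    FNN,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    clue,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
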