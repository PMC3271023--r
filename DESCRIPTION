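Package: gliomaTME
Title: Stochastic Population Dynamics of the Glioma Tumor Microenvironment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the co-evolution of glioma cells, glioma stem-like
    cells, astrocytes and microglia coupled through a cytokine signaling
    network. Cell populations follow logistic growth with Hill-function
    cross-regulation by soluble mediators, an angiogenesis gate driven by
    VEGF, and three stochastic layers (truncated Gaussian noise on secretion
    rates, sine-Wiener bounded noise on proliferation and conversion rates,
    and Poisson jump events for discrete recruitment). Provides virtual
    patient profiles, trigger-based therapy interventions (microglia
    depletion, cytokine blockade and combination therapy), finite-difference
    sensitivity analysis of a survival-proxy objective, seeded Monte Carlo
    ensembles and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    yaml,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
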