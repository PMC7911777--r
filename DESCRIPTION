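Package: spikeLR
Title: Linear Response Theory for Discrete-Time Spiking Neuronal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and linear-response analysis of a discrete-time
    stochastic leaky integrate-and-fire network with Gaussian noise.
    Provides the network model (transition probabilities, normalized Gibbs
    potential), a seeded trial-ensemble simulator, monomial observables with
    Hammersley-Clifford decomposition, spontaneous-activity correlation
    estimators, two first-order response predictors that map a weak
    time-dependent stimulus onto the change in the average of any
    finite-range spike observable, and an exact Markov-chain oracle for
    small networks used to validate every stochastic estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
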