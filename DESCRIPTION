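Package: bgnet
Title: Basal Ganglia-Thalamus Network Simulation and Deep Brain Stimulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley type) simulation of the
    subthalamic nucleus (STN), globus pallidus externa/interna (GPe/GPi)
    and thalamus as a directed network with small-world pallidal
    connectivity, sparse subthalamic connectivity and index-matched
    inter-nuclear wiring.  Reproduces normal, Parkinsonian and deep brain
    stimulation (DBS) regimes via striatal drive currents and
    high-frequency pulse trains, and derives the macroscopic observables
    used to assess frequency-dependent DBS efficacy: the Kuramoto
    synchronisation index of GPi spiking, mean GPi synaptic activity,
    thalamic response efficacy to sensorimotor input, Shannon entropy of
    the order parameters, and the log-log slope of the activity power
    spectrum.  The integrator is an adaptive Bogacki-Shampine
    Runge-Kutta 3(2) pair implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    igraph,
    optparse
Config/testthat/edition: 3
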