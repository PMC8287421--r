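Package: wcdelay
Title: Delay-Coupled Wilson-Cowan Networks with Homeostatic Inhibitory
    Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and synchronization analysis of networks of
    Wilson-Cowan neural-mass nodes coupled through delayed excitatory
    connections, with a homeostatic inhibitory weight that drives each
    excitatory population toward a target activity. Provides a fixed-step
    Runge-Kutta delay-differential-equation integrator with dense output,
    generators for ring, lattice and random row-normalized connectivity
    with homogeneous or Beta-distributed heterogeneous delays, linear
    stability analysis of the single self-coupled node (delay
    characteristic equation, Hopf boundary continuation, orbit diagrams
    and period-doubling detection), and a delay Master Stability Function
    built on a chain discretization of the delayed variational system,
    used to predict which network topologies hold a stable synchronous
    solution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
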