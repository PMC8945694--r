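Package: phasim
Title: Respiration Kinetics and Process Simulation for Mixed-Culture PHA Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models polyhydroxyalkanoate (PHA) storage by mixed microbial
    cultures fed volatile fatty acids. Provides a batch pulse-respiration
    forward model with hysteretic upshift/downshift Monod uptake kinetics, a
    synthetic respirogram generator (oxygen probe lag plus logger noise), a
    six-step respirometric parameter-estimation pipeline (aeration mass
    transfer, endogenous and polymer respiration, oxygen yield, substrate
    affinity and induction constants), and a Monte Carlo two-zone
    continuous-flow accumulation simulator in which a high-concentration
    stimulation zone decouples volumetric productivity from substrate
    utilization efficiency.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
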