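Package: motorcargo
Title: Motor-Driven Cargo Transport with Non-Markovian Detachment Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and single-particle-tracking analysis of intracellular
    cargo transport by molecular motors on microtubules. Implements an
    overdamped Langevin cargo coupled to a stepping motor through an elastic
    tether, with force-dependent stepping, constant attachment and either
    Markovian (constant, Arrhenius load factor) or non-Markovian
    (run-length-dependent) detachment kinetics, plus exact and spectral
    fractional Gaussian noise generators for sub-diffusive cargo motion.
    Provides time-averaged trajectory statistics (TAMSD, TAMD, TAVAR,
    anomalous exponents, mean first passage times, pooled window-velocity
    distributions), heterogeneous-motor residence-time models (discrete and
    gamma rate mixtures, cooperative birth-death motor ensembles) with
    samplers and tail-exponent estimation, and scenario experiments for
    blocked filaments and neighbouring-filament reach probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
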