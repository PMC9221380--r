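Package: lcsim
Title: Spiking-Neuron Simulation of the Locus Coeruleus Core with
    Noradrenergic Volume Transmission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate small networks of two-compartment
    conductance-based locus coeruleus (LC) neurons with
    calcium-dependent norepinephrine release, alpha2-receptor/GIRK
    mediated inhibition, and extracellular volume transmission.
    Includes a point-source diffusion model of extracellular
    norepinephrine with reuptake and receptor-binding kinetics, the
    derivation of an effective diffusion-driven GIRK kernel, spike-train
    and action-potential feature extraction, and a synthetic
    three-dimensional LC geometry generator with nearest-neighbour
    distance statistics and a parametric double-exponential fit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
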