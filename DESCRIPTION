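Package: silentnet
Title: Silent-Neuron Perturbations of Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of current-based integrate-and-fire
    cortical network models in which a chosen fraction of a chosen neuronal
    subpopulation is rendered synaptically silent by a constant
    hyperpolarizing "damage" current, as a model of neuronal hyperploidy.
    Provides the network builder and simulator (three populations:
    excitatory, leader and interneuron), silencing perturbations, firing-rate
    and field-signal metrics, Welch spectral band powers
    (delta/theta/beta/gamma), orchestration of silencing sweeps with Pearson
    correlation and two-way ANOVA/Tukey statistics, and synthetic fixtures
    (Poisson rasters, sinusoid traces, synthetic sweep records) for testing
    every analysis stage without the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
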