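Package: lalcpg
Title: Insect Lateral Accessory Lobe Spiking Central Pattern Generators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of spiking neural network central pattern
    generators inspired by the insect lateral accessory lobe (LAL). Provides
    adapting leaky integrate-and-fire neurons with conductance-based synapses
    and multiplicative noise, two LAL-inspired architectures (a 6-neuron Core
    half-centre network and a 12-neuron Comprehensive network with split
    velocity/turning motor control), an embodied animat with differential-drive
    and Ackermann-like kinematics, trajectory segmentation with sinuosity and
    stability metrics, movement-phenotype classification, parameter-space
    sweeps with exclusion rules, PCA over selected genotypes, and
    noise-robustness experiments. All results are returned as tibbles and
    chain with the pipe; fitted objects carry tidy(), glance() and autoplot()
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
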