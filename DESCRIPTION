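Package: dropscreen
Title: Design and Simulation of Droplet-Microfluidic Functional Metagenomic Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative models for droplet-microfluidic screening of
    metagenomic libraries against mammalian cells: Poisson single-particle
    encapsulation statistics, droplet geometry and merge-dilution accounting,
    binomial/Poisson apoptosis readout models for single cells and cell
    aggregates with background noise, threshold sorting, a Monte Carlo
    simulator of the full screening workflow, and enrichment estimation with
    exact binomial confidence intervals for spike-in experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
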