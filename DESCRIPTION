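Package: spiketopo
Title: Topological Analysis of Spike Trains from FORCE-Trained Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent networks of leaky integrate-and-fire neurons
    with double-exponential synaptic filtering, trains their linear readout by
    FORCE (recursive least squares with output feedback) to autonomously draw
    closed planar curves (a circle and multi-petal polar roses), and
    characterizes the resulting spike trains: Victor-Purpura spike-train
    distance matrices, rank-order normalization, and Vietoris-Rips persistent
    homology (persistence barcodes and Betti curves in dimensions 0 and 1).
    Includes a generator of surrogate phase-locked ("petal-modulated") Poisson
    rasters so the metric and topology stages can be exercised without
    training a network.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
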