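Package: fpiMEA
Title: Field Potential Imaging Analysis for Ultra-High-Density MEA
    Recordings of Brain Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for field potential imaging (FPI) data from
    dense CMOS microelectrode arrays recording brain organoids and
    assembloids. Provides a recording container with grid geometry,
    segment-wise least-squares detrending and zero-phase FIR filtering,
    threshold-based spike detection with waveform noise rejection, network
    burst detection, merging of co-active nearby electrodes into single
    somas, surrogate-based pairwise spike synchrony (z-scores) and
    functional connection graphs, propagation velocity and propagation
    area endpoints for network-wide oscillation events, per-electrode
    frequency band power maps with k-means spatial clustering, normalized
    inter-region connection strength for assembloids, and a group
    comparison layer (one-way ANOVA, Monte Carlo Dunnett test, eta
    squared, Cohen's d). A synthetic recording generator with full ground
    truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    multcomp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
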