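Package: kcdyn
Title: Clonal Dynamics and 3D Spatial Statistics of Transient Neurogenic Foci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative models of injury-induced striatal astrocyte
    neurogenesis organised around transient proliferative clusters (Ki67
    clusters, KCs). Provides a steady-state renewal model of KC initiation
    and exhaustion with forward predictions for BrdU pulse-chase and
    tamoxifen lineage-tracing labeling indices; a stochastic clone-expansion
    model of transit-amplifying progenitor and neuroblast fate choice with
    time-accelerating differentiation propensities, an exact master-equation
    oracle, and simulated-likelihood fitting; 3D point-pattern statistics
    (nearest-neighbor G function with Monte-Carlo envelopes under complete
    spatial randomness, Moran's I with permutation nulls, Fisher pooling);
    KC detection and classification from cell tables; and a calibrated
    synthetic-data generator emulating reconstructed specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    tools,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
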