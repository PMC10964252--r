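Package: CardioPIV
Title: Particle Image Velocimetry Contractility Analysis for Cardiac
    Cells, Tissues and Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies contractile function of beating cardiac
    preparations (single cardiomyocytes, monolayers, engineered heart
    tissues, organoids) from brightfield videos. Consecutive frames are
    cross-correlated over a grid of interrogation windows (FFT-based
    particle image velocimetry) to obtain displacement vector fields,
    which are validated, aggregated into a mean deformation-speed trace,
    segmented into beats, and summarised as 22 functional parameters
    including beating rate, contraction/relaxation kinetics, deformation
    distances, relaxation decay times and an elasticity-based estimate of
    contractile stress and force. A seeded synthetic-video generator with
    analytic ground truth supports validation of every pipeline stage,
    and renderers produce vector-overlay, heatmap and annotated
    trace-plus-video outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    jsonlite,
    png,
    tiff,
    pracma
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
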