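Package: alpulse
Title: Spiking Network Model of Pulse Tracking in the Moth Antennal Lobe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Conductance-based integrate-and-fire simulation of a six-glomerulus
    moth antennal lobe circuit (projection neurons and local neurons with fast
    GABA-A-like, slow GABA-B-like and spike-triggered SK auto-inhibitory
    currents), driven by inhomogeneous Poisson odor, mechanosensory and
    background input. Includes pulse-tracking analyses for such circuits:
    spiking response length, response slope against pulse length, the
    autocorrelation-based pulse-following index, and the pulse-following rate
    (cutoff frequency), together with experiment drivers for pulse-length
    sweeps, conductance-strength sweeps, pulse-frequency sweeps and graded
    odor-tuning paradigms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
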