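Package: srnnip
Title: Spiking Recurrent Networks with Synchronized Threshold Plasticity for Time-Series Anomaly Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clock-driven simulator for randomly connected excitatory/inhibitory
    spiking networks of leaky integrate-and-fire neurons with two hardware-oriented
    learning rules: spike-driven synaptic plasticity (SDSP) gated by the
    postsynaptic membrane potential, and event-driven stepwise intrinsic
    plasticity that adapts each neuron's firing threshold from a calcium-like
    activity trace while keeping the SDSP learning thresholds synchronized to
    the firing threshold. Includes Poisson rate encoding of 1-D signals, a
    linear readout trained to predict the next input rate, a judgment-margin
    anomaly detector with ROC analysis, a parameter-sweep harness, and a seeded
    generator of ECG-like periodic waveforms with labeled morphology anomalies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
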