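Package: vdsp
Title: Voltage-Dependent Synaptic Plasticity for Unsupervised Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clock-driven simulation of leaky integrate-and-fire (LIF) and
    adaptive LIF neuron populations, together with the voltage-dependent
    synaptic plasticity (VDSP) learning rule: a multiplicative Hebbian update
    triggered on postsynaptic spikes and computed from the presynaptic
    membrane potential instead of stored spike times.  Includes the analytic
    mapping between membrane potential and pre/post spike-time difference for
    constant-current drive, a pair-based trace STDP baseline, rate and Poisson
    image encoders, a two-layer winner-take-all classification network with a
    compiled simulation core, unsupervised training with post-hoc neuron
    labelling, and a synthetic multi-class pattern generator so the full
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
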