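Package: updownnet
Title: Spontaneous Up/Down Dynamics in Sparse Spiking Networks with Synaptic Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of sparse random networks of Izhikevich and
    adaptive exponential integrate-and-fire (AdEx) neurons with conductance-based
    synapses driven by Ornstein-Uhlenbeck synaptic noise. Provides a stochastic-Heun
    network integrator with spike rasters and voltage/conductance traces, single-neuron
    phase-plane tools (nullclines, rest states, bifurcation currents, noise-driven
    first-spike times), population measures (time-dependent firing rate, spike-train
    and voltage power spectra, spectral entropy, phase-locking value, excitation-
    inhibition balance estimate, 1/f^n fits), threshold-based segmentation of network
    activity into up/down/rest states and active/quiescent periods with duration
    statistics, synthetic fixture generators for testing the measures, and experiment
    drivers for noise-versus-coupling state diagrams and duration-versus-noise scans.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
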