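Package: fsephys
Title: Fast-Spiking Neuron Electrophysiology: Waveform Features and
    Short-Term Inhibitory Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis and simulation of whole-cell recordings from
    fast-spiking cortical interneurons and their inhibitory synapses.
    Provides a plain-text sweep-bundle data model for current-clamp and
    voltage-clamp recordings; action-potential waveform feature
    extraction (dV/dt-based threshold, height, half-width, interspike
    potential, maximum slope, adaptation metrics); IPSC measurement with
    decay-corrected paired-pulse ratios, series-resistance-aware
    current-to-conductance conversion, and passive-property estimation
    from test pulses; group statistics (one-way ANOVA with Tukey-Kramer
    comparisons, mixed repeated-measures ANOVA with Greenhouse-Geisser
    correction, pooled t tests, bootstrap of sample means); and seeded
    synthetic-data generators, including a conductance-based
    fast-spiking neuron with a two-population delayed-rectifier
    potassium current and a resource-depletion model of synaptic
    depression, so that every analysis stage can be verified end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
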