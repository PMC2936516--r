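Package: gammares
Title: Gamma Oscillation Resonance in a Conductance-Based Model of Primary Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a two-dimensional sheet of Hodgkin-Huxley excitatory and
    inhibitory model neurons with distance-decayed recurrent connectivity and
    independent Poisson thalamocortical drive, and measures how the resonance
    between spontaneous and stimulus-driven gamma oscillations shapes cortical
    responsiveness. Provides an exponential-Euler network integrator (compiled),
    an inhomogeneous Poisson spike-train generator, spike-train analysis tools
    (population rate, averaged-periodogram power spectra with peak detection,
    ISI distributions, normalized correlograms, response probability and delay,
    gamma-phase assignment, phase-binned input-spike efficacy), and experiment
    drivers that sweep input modulation frequency and thalamocortical synaptic
    strength to map resonance points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
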