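Package: ctmbc
Title: Coupled Thalamocortical Model with a Bidirectional Channel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a two-module, eight-population
    thalamocortical neural mass model of absence seizures.  Two
    Taylor-type cortico-thalamic circuits (pyramidal, interneuron,
    specific relay nucleus and thalamic reticular nucleus populations)
    are coupled through a bidirectional long-range channel.  The package
    provides a compiled fixed-step Runge-Kutta integrator, four
    stimulation protocols targeting the reticular nuclei (deep brain
    stimulation, charge-balanced biphasic pulses, and coordinated reset
    in 1:0 and 3:2 schedules), a four-state dynamical classifier based
    on dominant frequency and spike counting, one- and two-parameter
    bifurcation sweeps over the excitatory thalamic pathways, and
    therapy metrics (spike-wave-discharge area, percentage reduction,
    and RMS stimulation current).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
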