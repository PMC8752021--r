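Package: evoxplore
Title: Automatic Parameter Exploration for Stochastic Evolutionary Simulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tunes the parameters of stochastic Monte-Carlo evolutionary
    simulators by a normalized finite-difference gradient ascent with
    per-parameter direction memory, together with a coordinate-ascent
    variant and a progressive (staged, warm-started) learning schedule.
    The objective is any scalar readout of a simulation run. Two
    origin-of-life testbed simulators are bundled: an RNA-pool model on a
    toroidal grid in which a nucleotide synthetase ribozyme (NSR) may
    spread by favoring its own replication, and a lattice replicator
    model with three trans-acting activity classes in which mean
    replicator length can evolve upward under limited dispersal.
    Experiments are driven by YAML configurations, fully seeded, and
    emit TSV learning traces and simulation time series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
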