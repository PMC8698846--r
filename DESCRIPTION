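Package: respilab
Title: Simulation and Analysis of High-Resolution Respirometry
    Coupling-Control Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and analysis of closed-chamber oxygraph
    (high-resolution respirometry) experiments running a
    substrate-uncoupler-inhibitor titration (SUIT) coupling-control and
    cell-viability protocol on platelet samples. Simulates 2-second-sampled
    oxygen concentration traces with titration event marks, instrumental
    background flux and a planted dead-cell fraction; estimates
    volume-specific oxygen flux by windowed least-squares slopes and
    converts it to per-cell oxygen flow; extracts one steady-state flux per
    protocol state; and derives flux control ratios, the respirometric
    viability index, cytochrome-c control efficiency and effective
    titration concentrations. Cohort-level tools compare platelet isolation
    methods (density-gradient centrifugation, apheresis, washed apheresis)
    by ratios of group medians and relate platelet activation markers to
    respiration through an axis-symmetric dual regression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'chamber.R'
    'protocol.R'
    'simulate.R'
    'cohort-sim.R'
    'cohort.R'
    'flux.R'
    'metrics.R'
    'trace-io.R'
    'pipeline.R'
    'show-methods.R'
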