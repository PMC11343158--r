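Package: patchwalk
Title: Yield Models and Simulation for Coordinated Dual-Pipette Patch Clamp
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale tools for planning and evaluating "patch-walking",
    a multi-pipette patch-clamp strategy in which one pipette at a time is
    cleaned and advanced to a new cell while the other holds its whole-cell
    recording, chaining paired recordings across a brain slice. Provides
    closed-form counts of probed synaptic connections for the traditional
    and patch-walking strategies, a distance-dependent synaptic connection
    probability model with binomial yield statistics, the coordinated
    pipette scheduling rules as a testable state machine, per-attempt
    patch-clamp stage criteria (neuron hunting, gigaseal, break-in, quality
    control), synthesis and detection of evoked postsynaptic currents in
    bidirectional connection screens, seeded generators for cell maps and
    resistance traces, and a Monte Carlo discrete-event simulator that
    compares strategy efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
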