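Package: spikegc
Title: Directed Functional Connectivity of Spike Trains via Non-Negative
    Embedding and Conditional Granger Causality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-neuron spike-train recordings from
    behaving animals. Converts discrete spike trains into continuous
    instantaneous firing-rate series, embeds each trial in a low-rank
    non-negative latent space with rank selection by variance accounted for,
    constructs sliding-window directed functional-connectivity networks by
    conditional Granger causality with F-tests and false-discovery-rate
    pruning, and summarises network dynamics through causal density and
    global efficiency time courses aligned to a behavioural reference time.
    A point-process simulator with known ground-truth latent coupling is
    included so every stage can be validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
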