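Package: replaymap
Title: Compositional Hippocampal Maps, Constructive Replay and Replay Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for compositional models of the
    hippocampal formation. Builds discrete grid worlds and continuous arenas,
    object-vector and grid population codes and their conjunctions, key-value
    memories tracked under noisy path integration, supervised policy networks
    over compositional state representations, and constructive replay that
    writes vector memories at remote locations (contrasted with Bellman
    backups). Also implements a replay-analysis pipeline: occupancy-normalised
    rate maps, population-rate replay-event segmentation, memoryless Bayesian
    position decoding with leave-one-neuron-out spike-location interpolation,
    replay-spike-aligned rate-map change maps, home/elsewhere event
    classification with time-matched controls, and change-generalisation
    statistics, validated end to end on a synthetic hippocampal population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
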