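Package: nodetrans
Title: Node-Centered Quantification of Axonal Organelle Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify in vivo axonal transport of organelles
    (signaling endosomes, mitochondria) as they transit the node of Ranvier.
    Reads particle tracks (CSV or a TrackMate-style XML subset), projects
    spots onto an axon centerline to obtain signed node-centered positions,
    detects pauses, trims terminal pauses, qualifies tracks, bins
    frame-to-frame movements along the axon and summarizes mean moving
    velocity and pause frequency per subdomain (proximal internode, nodal
    constriction, distal internode). Also classifies mitochondrial
    directionality, computes per-minute flux and length statistics,
    quantifies organelle accumulation from fluorescence line profiles, and
    measures nodal constrictions in diameter profiles. A stochastic track
    generator with named presets provides ground truth for parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
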