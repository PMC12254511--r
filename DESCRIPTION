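Package: synconnect
Title: Functional Connectivity and Single-Neuron Physiology of Midbrain
    Dopamine Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring functional connectivity networks of
    midbrain dopamine neurons from somatic calcium-imaging traces and for
    quantifying single-neuron electrophysiology from patch-clamp sweeps.
    Builds significance-gated Spearman rank-correlation networks from
    neuron-by-frame fluorescence matrices, computes weighted and binary
    graph statistics (normalized node degree, node strength, clustering
    coefficient, network density, global efficiency), and runs a
    distance-versus-correlation spatial control. Companion
    electrophysiology tools measure spontaneous firing frequency, action
    potential half-width, ramp-based membrane capacitance, and resilience
    to a prolonged hyperpolarization challenge. A fully seeded synthetic
    data generator emulates fast calcium-indicator recordings (pacemaker
    spike trains convolved with a calibrated double-exponential
    fluorescence kernel) and stylized current- and voltage-clamp
    protocols, so every stage of the pipeline can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    igraph,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
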