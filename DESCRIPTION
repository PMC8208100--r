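Package: spinephys
Title: Electrophysiological Feature Extraction and Classification of Spinal Dorsal Horn Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-cell patch-clamp recordings from spinal
    dorsal horn neurons, including projection-neuron studies: passive membrane
    properties from seal-test sweeps, spike detection by dV/dt criterion,
    action-potential waveform and discharge metrics, rule-based classification
    of discharge patterns (tonic, delayed, gap, initial-burst, single-spike,
    phasic, reluctant) and afterhyperpolarisation profiles, P/N leak
    subtraction and classification of subthreshold voltage-activated currents
    (fast/slow A-type potassium, T-type-like calcium, Ih sag), sliding-template
    detection of spontaneous excitatory postsynaptic currents with event
    statistics, Ward hierarchical clustering with silhouette-based cluster
    number selection, group-comparison statistics, and a Henderson-equation
    liquid junction potential calculator. A conductance-based synthetic
    recording generator with ground-truth labels supports validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
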