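Package: acrodyn
Title: Discrete Logical Dynamics of the Human Sperm Acrosome Reaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-valued, synchronous, deterministic logical-network engine
    and analysis battery for signaling models of the human sperm acrosome
    reaction (AR). Provides attractor discovery by random restart, functional
    classification of attractors by their progesterone response (Spontaneous,
    Inducible, Negative), heterogeneity-aware initial-state ensembles with
    per-node activation statistics, acrosomal-pH clamping experiments,
    single-node transient perturbation screens, truth-table row perturbations,
    and an in-silico experimental-condition harness. A 38-node AR network
    reconstructed from the published mechanistic description is bundled as the
    reference model, together with a JSON network-file format, random-network
    fixtures and an exhaustive brute-force oracle for engine validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
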