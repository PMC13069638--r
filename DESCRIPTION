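Package: becdyn
Title: Biphasic, Emergent, and Coexistent Dynamics of Signed Regulatory Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained modeling of small signed regulatory circuits with
    Hill-type activation and inhibition kinetics, built around a five-component
    model of TNF-induced cell death in which RIP1 tunes the balance between
    apoptosis (caspase-8) and necroptosis (phosphorylated RIP3). Provides a
    compiled deterministic integrator with steady-state and multistability
    detection, dose-response generation under expression scaling
    (knockdown/knockout), quantitative classifiers for biphasic, emergent, and
    coexistent (BEC) dynamics, Langevin simulation with trajectory-density
    potential landscapes, dwell-time Shannon entropy of death-mode occupancy,
    Latin hypercube random-parameter screening, and exhaustive two- and
    three-node topology-to-function mapping with incoherent feedforward loop
    (IFFL) detection and a topological atlas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    yaml,
    jsonlite,
    lhs,
    minpack.lm,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
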