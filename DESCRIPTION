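Package: ratchetpath
Title: Ratchet-Biased Unbinding Simulations and Binding-Intermediate Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for locating and characterizing metastable
    intermediates on protein-ligand unbinding pathways. Implements biased
    molecular dynamics (BMD) with a ratchet-and-pawl reaction-coordinate
    bias and an adaptive force-constant schedule, a Langevin-dynamics toy
    simulator on model energy landscapes with flat-bottom (NOE-style)
    distance restraints, joint multi-channel metastable-plateau detection
    with a minimum-lifetime rule, cluster-based acceptance of candidate
    intermediates, and the downstream structural analysis: superposition
    RMSDs under all-atom and group-excluded alignments, per-moiety
    center-of-mass distances, per-atom RMSF, contact census with
    permanent/transient classification, moiety-by-residue contact maps,
    bridging-water counts, and hydrogen-bond geometry statistics. Reads and
    writes PDB structures and DCD/XYZ trajectories.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
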