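Package: soxdimer
Title: Restraint-Based Modelling of DNA-Dependent SOX Group E Dimerization
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how SOX Group E transcription factors
    (SOX8/SOX9/SOX10) dimerize on tandemly inverted DNA sites. Provides
    degenerate motif scanning and palindrome analysis of duplex probes,
    helical-wheel projection and hydrophobic-face detection for the
    amphipathic dimerization helix, four-parameter logistic fitting of
    EMSA titrations with Hill-coefficient and kinetic back-calculation,
    a coarse-grained B-DNA builder with site-directed bending and
    bend-angle measurement, a typed flat-bottom restraint engine with
    ambiguous interaction restraints (AIRs), rigid-body docking with
    energy ranking and orientation clustering, and simulated-annealing
    assembly of the complete dimeric protein-DNA complex at one bead per
    residue and one frame per base pair.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    minpack.lm,
    jsonlite,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
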