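Package: fireflyfold
Title: Firefly-Inspired Population Annealing for Lattice Protein Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Protein structure prediction on three-dimensional cubic and
    face-centred-cubic lattices using a firefly-inspired, population-based
    simulated-annealing heuristic. Conformations are self-avoiding walks
    scored with the hydrophobic-polar (HP100) energy or a 20x20 pairwise
    contact-energy matrix (Miyazawa-Jernigan style). The conformational
    neighbourhood is the reversible pull-move set; one population member is
    driven by Metropolis acceptance under a geometric cooling schedule while
    the remaining members are attracted structurally towards the current
    best conformation. Includes exhaustive enumeration oracles for small
    chains, packaged benchmark sequences with published reference energies,
    objective-function-evaluation accounting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
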