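Package: qgdesign
Title: Grover Search Circuits for Protein Sequence Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and simulates gate-based quantum circuits that solve small
    protein sequence design problems with Grover's algorithm. Sequences over a
    residue alphabet are scored by pairwise contact energy models (an integer
    simplified model, a distance-weighted fixed-point model, and a two-letter
    hydrophobic-polar model); the Grover oracle computes each sequence's total
    energy with reversible ripple-carry adders and a shift-and-add multiplier,
    compares it against a threshold, and flips the phase of sequences below it.
    Includes a classical reference implementation of the energy models, a gate-level
    circuit representation with statevector and reversible basis-state evaluation
    backends, qubit and gate-count resource accounting, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
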