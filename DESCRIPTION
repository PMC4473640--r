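Package: transverseq
Title: Transverse-Current Nanopore Sequencing Simulation and
    Correlation-Aware Base Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the transverse tunneling current read out
    nucleotide-by-nucleotide from a single-stranded DNA or RNA chain
    modeled as a multi-orbital tight-binding system between wide-band
    electrodes, and implements a statistical base-calling procedure
    (single-current maximum likelihood plus iterative joint-density
    Bayesian refinement) with fidelity scoring.  Includes a synthetic
    generator for the reduced per-nucleotide Hamiltonian blocks,
    projector-operator effective Hamiltonians over non-orthogonal bases,
    Green's-function (Landauer/Meir-Wingreen) transport, non-parametric
    joint current-density calibration, and an end-to-end pipeline that
    quantifies and corrects the intrinsic structural noise caused by
    neighboring bases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
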