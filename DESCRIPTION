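Package: wormfish
Title: Sequential smFISH Analysis for Whole-Mount C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of sequential single-molecule FISH (smFISH)
    experiments in whole-mount C. elegans: oligo probe panel design with GC,
    off-target and cross-hybridization screens; image background correction,
    gamma adjustment and low-pass filtering; DAPI-based drift registration by
    phase correlation; Laplacian-of-Gaussian spot detection with dense-region
    decomposition and two-channel colocalization QC; probabilistic
    transcript-to-nucleus assignment through a geometry-weighted Gaussian
    mixture parameterized by per-slice nuclear ellipse fits; and cell-by-gene
    quantification with neuron-class profiling and reference-table
    comparisons. A synthetic-data generator renders ground-truth experiments
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
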