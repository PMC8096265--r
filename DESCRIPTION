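Package: checs
Title: Pooled Reporter-Screen Scoring, Equilibrium Binding Fits and qPCR Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis of chromatin effector coregulator screens (ChECS): pooled
    shRNA screens read out by FACS sorting of a fluorescent silencing reporter.
    Quantifies 22-nt guide strands from sequencing reads by exact matching,
    scores guides by the geometric-mean enrichment of the reporter-positive over
    the reporter-negative population across replicates, ranks genes with
    per-replicate Poisson tests combined by Fisher's method and a Bonferroni
    correction, fits single-site equilibrium binding titrations (fluorescence
    anisotropy) for dissociation constants, and performs input/spike-in
    normalized relative quantification of ChIP- and DRIP-qPCR with the
    treated-versus-control replicate scaling and one-tailed t-test used for
    reporting. A synthetic-data module generates library manifests, sorted
    screens with planted hits, FASTQ reads, titrations and Cq tables with known
    ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
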