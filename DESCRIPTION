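Package: mslseq
Title: Sequence Signatures of MSL-Complex Targeting from k-mer Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discriminative sequence-word (k-mer) analysis of dosage
    compensation in Drosophila: derives the six gene-feature sequence
    classes from a genome and annotation, builds AT-normalized 2-6 bp
    word-frequency matrices, discriminates strongly from weakly MSL-bound
    genes with PCA and orthogonal partial least squares discriminant
    analysis (OPLS-DA), assembles predictive words into position weight
    matrix motifs with a logistic-regression-gated iterative aligner,
    calls peaks and gene-binding values from tiling signal tracks, and
    tests the 3'-bias of coding-sequence signatures. A synthetic-data
    generator with known ground truth emulates the study inputs so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
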