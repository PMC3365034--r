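Package: ddradkit
Title: Design and Reference-Free Analysis of Double-Digest RADseq Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for double-digest restriction-site-associated DNA
    sequencing (ddRADseq). A design simulator performs in-silico double
    restriction digests of any genome, models precise size selection as a
    normal sampling density over fragment length, and predicts how many
    genomic regions a given sequencing investment recovers at a target
    coverage, including the read count at which region discovery saturates.
    A reference-free analysis pipeline demultiplexes combinatorially
    indexed reads by in-line barcode and multiplex index, collapses
    identical reads into unique-sequence records with per-sample counts and
    averaged qualities, clusters unique sequences into putative ortholog
    groups with the Markov Cluster algorithm over an alignment-identity
    graph, removes paralogous and repetitive clusters with a ploidy-aware
    haplotype-count filter, and emits pseudo-reference FASTA plus SAM
    alignments ready for standard genotypers. A synthetic-data module
    generates genomes, diverged parental lines, and barcoded error-bearing
    reads with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    igraph,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
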