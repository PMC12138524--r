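Package: lncscreen
Title: Long Noncoding RNA Identification and Stress-Tolerance Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for identifying long noncoding RNAs
    (lncRNAs) from assembled transcripts and screening them for
    stress-tolerance relevance across two contrasting genotypes. Implements
    length/known-transcript filtering, five-way consensus coding-potential
    classification, FPKM quantification and pooled-count differential
    expression with Benjamini-Hochberg FDR control, strand-aware cis target
    assignment within a genomic window with a six-way positional subtype
    taxonomy, trans target assignment gated by a nearest-neighbor RNA-RNA
    hybridization energy, cross-genotype three-state contrast screening and
    key-pair selection, miRNA hairpin precursor scanning, hypergeometric
    over-representation, and qPCR delta-delta-Ct concordance. A synthetic
    data generator with a planted ground-truth manifest makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
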