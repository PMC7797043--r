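Package: deepfun
Title: Multitask Convolutional Modeling of Dense Epigenomic Maps and
    Regulatory Variant Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains multitask convolutional neural networks that map 1000 bp
    DNA sequence windows to the presence of chromatin features (DNase-seq
    accessibility, histone marks, transcription-factor binding), scores
    non-coding variants by the SNP Activity Difference (SAD, the change in
    predicted activity between alternative and reference alleles), interprets
    first-layer convolutional filters as position weight matrices
    (information content, motif matching, nullification influence), and
    prioritizes GWAS loci into regulatory trait-associated genes with pLI and
    tissue-specific-expression enrichment plus canonical correlation of
    variant effects against tissue. A fully synthetic planted-motif fixture
    generator makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
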