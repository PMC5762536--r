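Package: locusnet
Title: Integrative lncRNA-mRNA-miRNA Expression Analysis with
    Cis-Regulation and Imprinted-Locus Silencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for paired tumour/control expression profiling of
    protein-coding transcripts, long non-coding RNAs (lncRNAs) and
    miRNAs: quantile normalization, fold-change plus t-test
    differential screening with Benjamini-Hochberg correction,
    strand-aware positional classification of lncRNAs (sense,
    antisense, bidirectional, intergenic, intronic), Pearson
    co-expression network construction between differentially
    expressed lncRNAs and mRNAs, genomic-window cis-regulation
    pairing, imprinted-locus miRNA silencing summaries, Fisher's-exact
    gene-set over-representation analysis, and 2^-ddCt qPCR relative
    quantification.  A synthetic-data generator emulating a 3 vs 3
    microarray design with a planted silenced imprinted locus (a
    DLK1-MEG3 style topology) makes the whole pipeline testable
    without raw arrays.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
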