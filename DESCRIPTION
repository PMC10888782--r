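Package: pollensc
Title: Single-Pollen Transcriptome and Methylome Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-pollen CEL-seq transcriptomes
    segregating DNA-glycosylase mutations: barcode demultiplexing and UMI
    counting, SNP-based haploid genotyping with sentinel genes, library
    complexity QC, correlation clustering, from-scratch negative-binomial
    Wald differential expression with Holm correction, CG/CHG gene-body
    methylation epiallele classification and methylated-pollen-gene
    selection, absolute-abundance timecourse normalization with Gaussian
    kernel smoothing, and pollen-area bimodality analysis. Includes a
    synthetic-data generator with ground-truth labels for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
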