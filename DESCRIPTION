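Package: rxekit
Title: Chromosome-Level Relative X Expression Analysis for RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures dosage compensation of the mammalian X chromosome from
    RNA-seq expression tables using the relative X expression (RXE) statistic,
    the difference between mean (or median) log2 expression of X-linked genes
    and pooled autosomal genes. Provides the statistical treatments that shape
    RXE estimates (log2 transformation, Tukey-fence outlier removal,
    expression-threshold and zero-balanced trimming), an abstract read
    mapping-policy simulator covering unique, non-unique and spliced
    multi-mapping regimes with fractional 1/k assignment, FPKM quantification,
    paralog cis/trans, biotype and gene-set stratification, library-depth
    titration, and a synthetic-data generator that emulates paralog-enriched X
    chromosomes so every pipeline stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
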