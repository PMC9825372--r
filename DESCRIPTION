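Package: primeseq
Title: Paired Translatome and Histone-Mark Analysis of Exercise-Primed Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating neuronal translatome (TRAP-seq) differential
    expression with sparse histone-modification (CUT&RUN) coverage to identify
    genes epigenetically "primed" by early-life exercise. Implements negative
    binomial Wald and likelihood-ratio differential expression with
    median-of-ratios normalization, sparse-enrichment peak calling with
    IgG-control empirical-FDR thresholding, priority-ordered peak-to-gene
    annotation, candidate-gene classification across behavioral groups
    (cGAME/cGAMES/cGAMS), mark-dynamics priming fractions, binned-coverage
    Spearman concordance, and a synthetic paired study generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
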