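Package: tagseq3p
Title: Quantification and Seasonal Differential Expression for 3' Tag mRNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level quantification for 3' tag mRNA-seq (QuantSeq-style)
    libraries from aligned single-end reads: post-alignment quality filtering,
    overlap clustering of read hits, detection of soft-clipped polyA tails as
    transcript-end evidence, replicate-based cluster validation, and
    strand-aware assignment of clusters to annotated genes. Downstream tools
    cover low-expression filtering, median-of-ratios size factors, a log2
    variance-flattening transform, PCA and sample-correlation quality control,
    a negative-binomial Wald test for differential expression between time
    points, shared-DEG set decomposition across genotypes, and classification
    of re-regulated genes across consecutive season transitions. A synthetic
    data generator produces ground-truthed annotation, tag alignments, and
    count experiments so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    igraph
Config/testthat/edition: 3
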