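Package: qtlcanvas
Title: Genotype-Stratified QTL Coverage Plots, Credible-Set Filtering and
    Signal-Level Colocalisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for interpreting molecular quantitative trait loci (QTLs)
    from transcriptomic data. Builds intron-compressed coordinate maps for gene
    regions, extracts and genotype-stratifies per-sample read coverage,
    estimates exon-level QTL effect sizes with confidence intervals and FDR
    flags, filters transcript-level summary statistics via connected components
    of fine-mapped credible sets, and computes signal-level colocalisation
    posteriors (PP0-PP4) from per-variant log Bayes factors. Includes seeded
    synthetic-data generators emulating all required inputs, so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    ggplot2,
    cowplot,
    igraph,
    jsonlite,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
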