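Package: regmut
Title: Cis-Regulatory Somatic Mutation Analysis in Cancer Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for somatic cis-regulatory mutations and their
    impact on gene expression. Predicts transcription factor binding sites
    (TFBSs) inside ChIP-seq peaks by position weight matrix scanning at a
    relative-score threshold, quantifies somatic mutation rates in TFBSs,
    protein-coding exons and their flanking regions against shuffled-genome
    nulls, detects frequently targeted 1-kb windows and tests their promoter
    enrichment with the hypergeometric distribution, scores TFBS disruption by
    SNVs and indels via alternative-sequence re-scanning, and integrates
    mutation and expression data over a gene-interaction network with a
    hierarchical-Bayes model solved by belief propagation. A synthetic-data
    generator with planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    methods,
    GenomeInfoDb,
    data.table,
    jsonlite,
    igraph,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
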