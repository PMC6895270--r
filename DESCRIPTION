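Package: eisplit
Title: Exon-Intron Split Analysis of Transcriptional and
    Post-Transcriptional Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Separates transcriptional from post-transcriptional gene
    regulation in stranded paired-end RNA-seq by counting read pairs in
    exonic and intronic regions of non-overlapping genes (exon-intron
    split analysis, EISA). Estimates per-gene exonic and intronic log2
    fold-changes (dE, dI) and their difference (dE - dI, the mRNA
    stability component) with negative-binomial moderated tests,
    summarises the relative transcriptional and post-transcriptional
    contribution to differential expression, stratifies genes by
    predicted miRNA target sites for cumulative-distribution and
    Kolmogorov-Smirnov analyses, assigns differential histone-mark
    peaks to gene promoters, titrates sequencing depth by count
    thinning, and ships a seeded synthetic-data generator (annotation,
    counts, alignments, target predictions, differential peaks) with
    ground truth so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    edgeR,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
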