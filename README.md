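# eisplit

Exon–intron split analysis (EISA) of stranded paired-end RNA-seq:
separating **transcriptional** from **post-transcriptional** gene
regulation between two conditions.

Most of an mRNA's intronic sequence exists only in the nascent
transcript, so the abundance of intron-mapping reads tracks the rate of
transcription, while exon-mapping reads track the steady-state mRNA
pool. Comparing two conditions per gene:

- **ΔI** — log2 fold-change of intronic read abundance ≈ change in
  transcription rate;
- **ΔE** — log2 fold-change of exonic read abundance ≈ total mRNA
  change;
- **ΔE − ΔI** — the post-transcriptional component: change in mRNA
  stability, much of it miRNA-driven.

`eisplit` is for transcriptomics analysts who want to run this split on
their own alignments: it builds exon/intron gene models from a GTF
(non-overlapping genes only), classifies read pairs strand-specifically
(a pair is *exonic* if the 5′ end of the first read lands in an exon,
*intronic* if the first read lies wholly within an intron and more than
10 bp from any exon), tests both components with negative-binomial
moderated models (edgeR), and quantifies the relative contribution of
the two regulatory layers. Companion analyses cover miRNA target-site
stratified CDFs with pairwise Kolmogorov–Smirnov tests, promoter
histone-mark integration (MAnorm-style M-values), and sequencing-depth
titration. A seeded synthetic-data generator (annotation, counts,
alignments with per-pair truth labels, target predictions, differential
peaks) makes the whole pipeline testable without any external download.

## Worked example

Everything below is synthetic and seeded, so it reproduces exactly.

```r
library(eisplit)

# a 2,000-gene cohort: 30% transcription-only, 30% stability-only,
# 40% unregulated genes, |log2 effect| = 2, 3 vs 3 samples
cfg <- sim_config(seed = 1)
sim <- simulate_counts(cfg)

res <- eisa(sim$counts, sim$design)
head(res, 3)
#>   gene_id    dE       dI  dEmI  p_dI fdr_dI   p_dEmI fdr_dEmI ...
#> 1  G00001 2.783  0.02103 2.762 0.994  1.000 7.20e-13 1.44e-10
#> 2  G00002 0.162  0.01621 0.145 0.885  0.971 7.77e-01 9.29e-01
#> 3  G00003 1.719 -0.00181 1.721 0.998  1.000 9.58e-06 4.20e-05
```

`G00001` is called post-transcriptionally up-regulated: its exonic
abundance rises with no intronic change (ΔE ≈ 2.8, ΔI ≈ 0, ΔE−ΔI ≈
2.8, FDR ≈ 1e-10), so the change is attributed to mRNA stability, not
transcription — and indeed the generator planted it as a
stability-class gene.

```r
contribution_metric(res, threshold = 1)
#> contribution_summary: 1200 genes with |dE| > 1
#>   transcriptional: 0.5  post-transcriptional: 0.5  ties: 0
```

Of the differentially expressed genes (|ΔE| > 1), half change mainly
through transcription (|ΔI| > |ΔE−ΔI|) — as expected for the 30/30
planted mixture. Counting real alignments instead:

```r
models <- build_gene_models(read_annotation("annotation.gtf"))
counts <- count_bams(c(ctrl1 = "ctrl1.bam", trt1 = "trt1.bam", ...),
                     models, strandedness = "reverse")
res <- eisa(counts, design = c("ctrl", "trt", ...))
```

Downstream analyses: `stratified_cdf()` + `pairwise_ks()` for
target-site CDFs, `select_direct_targets()` for the top-N intersection
of post-transcriptional repression with prediction rank,
`assign_gene_m()` + `sliding_window_profile()` + `concordance_report()`
for promoter chromatin marks, `titrate()` for depth requirements, and
`run_pipeline()` to run all stages from one (YAML) config with a
checksummed manifest.

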