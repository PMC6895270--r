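# Shared fixtures, built in code.

# Two hand-made genes on one contig:
#   GA, '+': exons [101,200] and [301,400]  -> intron [201,300]
#   GB, '-': exons [1001,1100], [1201,1300], [1401,1500]
toy_exons <- function() {
  GenomicRanges::GRanges(
    seqnames = "chrT",
    ranges = IRanges::IRanges(
      start = c(101, 301, 1001, 1201, 1401),
      end = c(200, 400, 1100, 1300, 1500)),
    strand = c("+", "+", "-", "-", "-"),
    gene_id = c("GA", "GA", "GB", "GB", "GB"),
    transcript_id = c("GA.t1", "GA.t1", "GB.t1", "GB.t1", "GB.t1"))
}

toy_models <- function() build_gene_models(toy_exons())

# minimal read-pair observation on gene GA ('+' fragment)
toy_obs <- function(pos5, span_start = pos5, span_end = pos5 + 49,
                    strand = "+", chrom = "chrT", ...) {
  list(chrom = chrom, strand = strand, pos5 = pos5,
       span_start = span_start, span_end = span_end, ...)
}

# counts object with given matrices (shared dimnames generated)
toy_counts <- function(exonic, intronic, samples = NULL) {
  exonic <- as.matrix(exonic); intronic <- as.matrix(intronic)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(exonic)))
  genes <- sprintf("g%02d", seq_len(nrow(exonic)))
  dimnames(exonic) <- dimnames(intronic) <- list(genes, samples)
  eisa_counts(exonic, intronic)
}

# write SAM records + header and convert to an indexed BAM
sam_to_bam <- function(records, chrom = "chrT", len = 100000L,
                       prefix = tempfile("fix")) {
  sam <- paste0(prefix, ".sam")
  writeLines(c("@HD\tVN:1.6",
               paste0("@SQ\tSN:", chrom, "\tLN:", len), records), sam)
  Rsamtools::asBam(sam, destination = prefix, overwrite = TRUE,
                   indexDestination = TRUE)
}

# one properly-paired record pair (first read + mate) as SAM lines
sam_pair <- function(qname, pos, strand = "+", chrom = "chrT",
                     cigar = "50M", mapq = 255L, len = 50L) {
  flag1 <- if (strand == "+") 99L else 83L
  flag2 <- if (strand == "+") 147L else 163L
  seq <- strrep("A", len)
  c(paste(qname, flag1, chrom, pos, mapq, cigar, "=", pos, 0, seq, "*",
          sep = "\t"),
    paste(qname, flag2, chrom, pos, mapq, paste0(len, "M"), "=", pos, 0,
          seq, "*", sep = "\t"))
}

# independent brute-force two-sample K-S statistic: max CDF gap over the
# pooled sample points
ks_D_brute <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}
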