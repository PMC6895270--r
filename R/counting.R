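#' Classify one read pair as exonic, intronic or unassigned
#'
#' Applies the split-analysis classification rules to a single read-pair
#' observation. A pair is *exonic* if the 5' end of the first read falls in
#' an exonic region of a (strand-compatible) gene; *intronic* if the first
#' read's aligned span lies entirely within one intronic region with every
#' base more than `exon_buffer_bp` (default 10) away from the nearest exon;
#' otherwise *unassigned*. Non-unique pairs and pairs whose fragment strand
#' is incompatible with the gene under the chosen protocol are unassigned.
#' A spliced first read is exonic if any aligned block's 5' start is exonic
#' and can never be intronic.
#'
#' @param obs A list describing the first read of the pair:
#'   `chrom`; `strand` (fragment strand, `"+"`/`"-"`); `pos5` (1-based 5'
#'   end of the first read); `span_start`, `span_end` (1-based closed
#'   aligned span); optional `block_starts5` (5' starts of aligned blocks
#'   for spliced reads; its presence with length > 1 marks the read as
#'   spliced); optional `unique` (default `TRUE`).
#' @param models A `gene_models` object.
#' @param strandedness `"reverse"` (dUTP; default), `"forward"`, or
#'   `"unstranded"`.
#' @return `"exonic"`, `"intronic"` or `"unassigned"`.
#' @export
classify_read_pair <- function(obs, models,
                               strandedness = c("reverse", "forward",
                                                "unstranded")) {
  strandedness <- match.arg(strandedness)
  stopifnot(inherits(models, "gene_models"))
  spliced <- !is.null(obs$block_starts5) && length(obs$block_starts5) > 1L
  cls <- classify_core(
    chrom = obs$chrom,
    frag_strand = obs$strand,
    pos5 = obs$pos5,
    span_start = obs$span_start,
    span_end = obs$span_end,
    spliced = spliced,
    block_starts5 = if (spliced) list(obs$block_starts5) else list(obs$pos5),
    unique = if (is.null(obs$unique)) TRUE else obs$unique,
    models = models, strandedness = strandedness)
  cls$class
}

# Vectorized classifier. All coordinate vectors are parallel; block_starts5
# is a list of per-read 5' block starts (length-1 for unspliced reads).
# Returns data.frame(class, gene_id).
classify_core <- function(chrom, frag_strand, pos5, span_start, span_end,
                          spliced, block_starts5, unique, models,
                          strandedness) {
  n <- length(pos5)
  out_class <- rep("unassigned", n)
  out_gene <- rep(NA_character_, n)
  if (n == 0L) return(data.frame(class = character(), gene_id = character()))
  stranded <- strandedness != "unstranded"

  g <- models$genes
  # flattened exon union with gene index
  ex_flat <- unlist(models$exonic, use.names = FALSE)
  ex_gene <- rep(names(models$exonic), lengths(models$exonic))
  # introns shrunk by the buffer on both sides: a span entirely inside one of
  # these shrunken intervals is everywhere > buffer bp from the nearest exon
  buf <- models$exon_buffer_bp
  in_flat <- unlist(models$intronic, use.names = FALSE)
  in_gene <- rep(names(models$intronic), lengths(models$intronic))
  wide <- GenomicRanges::width(in_flat) > 2L * buf
  in_flat <- in_flat[wide]; in_gene <- in_gene[wide]
  if (length(in_flat)) {
    in_flat <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(in_flat),
      IRanges::IRanges(GenomicRanges::start(in_flat) + buf,
                       GenomicRanges::end(in_flat) - buf),
      strand = GenomicRanges::strand(in_flat))
  }

  strand_of_gene <- stats::setNames(g$strand, g$gene_id)
  ok <- unique
  seqs <- unique(chrom)

  # exonic: any 5' block start (pos5 itself for unspliced reads) in an exon
  bs_n <- lengths(block_starts5)
  pts <- GenomicRanges::GRanges(
    rep(chrom, bs_n),
    IRanges::IRanges(unlist(block_starts5), width = 1L))
  GenomeInfoDb::seqlevels(pts) <- union(GenomeInfoDb::seqlevels(pts),
                                        GenomeInfoDb::seqlevels(ex_flat))
  hit <- GenomicRanges::findOverlaps(pts, ex_flat, ignore.strand = TRUE)
  read_of_pt <- rep(seq_len(n), bs_n)
  if (length(hit)) {
    ridx <- read_of_pt[S4Vectors::queryHits(hit)]
    gene_hit <- ex_gene[S4Vectors::subjectHits(hit)]
    # genes are non-overlapping: at most one gene per point; keep first hit
    first <- !duplicated(ridx)
    ridx <- ridx[first]; gene_hit <- gene_hit[first]
    compat <- !stranded | frag_strand[ridx] == strand_of_gene[gene_hit]
    sel <- ok[ridx] & compat
    out_class[ridx[sel]] <- "exonic"
    out_gene[ridx[sel]] <- gene_hit[sel]
  }

  # intronic: unspliced span entirely within a buffered intronic interval
  cand <- which(out_class == "unassigned" & ok & !spliced)
  if (length(cand) && length(in_flat)) {
    spans <- GenomicRanges::GRanges(
      chrom[cand], IRanges::IRanges(span_start[cand], span_end[cand]))
    GenomeInfoDb::seqlevels(spans) <- union(GenomeInfoDb::seqlevels(spans),
                                            GenomeInfoDb::seqlevels(in_flat))
    hit <- GenomicRanges::findOverlaps(spans, in_flat, type = "within",
                                       ignore.strand = TRUE)
    if (length(hit)) {
      ridx <- cand[S4Vectors::queryHits(hit)]
      gene_hit <- in_gene[S4Vectors::subjectHits(hit)]
      first <- !duplicated(ridx)
      ridx <- ridx[first]; gene_hit <- gene_hit[first]
      compat <- !stranded | frag_strand[ridx] == strand_of_gene[gene_hit]
      out_class[ridx[compat]] <- "intronic"
      out_gene[ridx[compat]] <- gene_hit[compat]
    }
  }
  data.frame(class = out_class, gene_id = out_gene, stringsAsFactors = FALSE)
}

#' Classify every read pair of an alignment file
#'
#' Reads the first-in-pair alignments of a BAM and returns the per-pair
#' classification used by [count_bam()]. Useful for auditing the
#' classifier against a labelled synthetic BAM.
#'
#' @inheritParams count_bam
#' @return data.frame `qname`, `class` (`exonic`/`intronic`/`unassigned`),
#'   `gene_id` (`NA` when unassigned), `unique`.
#' @export
classify_bam <- function(bam, models,
                         strandedness = c("reverse", "forward",
                                          "unstranded"),
                         min_mapq = 255L, single_end = FALSE) {
  strandedness <- match.arg(strandedness)
  stopifnot(inherits(models, "gene_models"))
  if (!file.exists(bam)) stop("BAM not found: ", bam)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index (.bai) missing for: ", bam)

  flag <- if (single_end) {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE)
  } else {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isProperPair = TRUE,
                           isFirstMateRead = TRUE,
                           isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE)
  }
  param <- Rsamtools::ScanBamParam(flag = flag, what = "mapq")
  gal <- GenomicAlignments::readGAlignments(Rsamtools::BamFile(bam),
                                            param = param,
                                            use.names = TRUE)
  if (length(gal) == 0L)
    return(data.frame(qname = character(), class = character(),
                      gene_id = character(), unique = logical()))
  bam_chroms <- unique(as.character(GenomicAlignments::seqnames(gal)))
  ann_chroms <- unique(models$genes$chrom)
  orphan <- setdiff(bam_chroms, ann_chroms)
  if (length(orphan) == length(bam_chroms))
    stop("no BAM chromosome matches the annotation; BAM has: ",
         paste(utils::head(orphan, 10), collapse = ", "))

  mq <- S4Vectors::mcols(gal)$mapq
  uniq <- !is.na(mq) & mq >= min_mapq
  read_strand <- as.character(GenomicAlignments::strand(gal))
  frag_strand <- switch(strandedness,
    reverse = ifelse(read_strand == "+", "-", "+"),
    forward = read_strand,
    unstranded = read_strand)
  pos5 <- ifelse(read_strand == "+", GenomicAlignments::start(gal),
                 GenomicAlignments::end(gal))
  spliced <- GenomicAlignments::njunc(gal) > 0L
  block_starts5 <- as.list(pos5)
  if (any(spliced)) {
    blocks <- GenomicAlignments::grglist(gal[spliced])
    bs <- as.list(GenomicRanges::start(blocks))
    be <- as.list(GenomicRanges::end(blocks))
    neg <- read_strand[spliced] == "-"
    bs[neg] <- be[neg]
    block_starts5[spliced] <- bs
  }
  cls <- classify_core(
    chrom = as.character(GenomicAlignments::seqnames(gal)),
    frag_strand = frag_strand, pos5 = pos5,
    span_start = GenomicAlignments::start(gal),
    span_end = GenomicAlignments::end(gal),
    spliced = spliced, block_starts5 = block_starts5,
    unique = uniq, models = models, strandedness = strandedness)
  data.frame(qname = names(gal), class = cls$class, gene_id = cls$gene_id,
             unique = uniq, stringsAsFactors = FALSE, row.names = NULL)
}

#' Count exonic and intronic read pairs in one alignment file
#'
#' Streams the first-in-pair reads of a coordinate-sorted, indexed BAM and
#' classifies each properly paired, uniquely mapped pair with the rules of
#' [classify_read_pair()], accumulating per-gene exonic and intronic counts.
#' Each pair contributes to at most one gene and one class.
#'
#' @param bam Path to a sorted BAM with a `.bai` index.
#' @param models A `gene_models` object.
#' @param strandedness Library protocol: `"reverse"` (dUTP; the fragment is
#'   antisense to the first read), `"forward"`, or `"unstranded"`.
#' @param sample_id Label for the column; defaults to the BAM basename.
#' @param min_mapq Minimum mapping quality regarded as uniquely mapped
#'   (default 255, the unique-mapper convention of STAR-style aligners).
#' @param single_end If `TRUE`, treat every primary alignment as a "first
#'   read" (no proper-pair requirement).
#' @return A list with `counts` (data.frame `gene_id`, `exonic`,
#'   `intronic`), `library_sizes` (named vector, exonic/intronic totals) and
#'   `diagnostics` (tallies of pairs seen, non-unique, exonic, intronic,
#'   unassigned).
#' @export
count_bam <- function(bam, models,
                      strandedness = c("reverse", "forward", "unstranded"),
                      sample_id = NULL, min_mapq = 255L,
                      single_end = FALSE) {
  strandedness <- match.arg(strandedness)
  if (is.null(sample_id)) sample_id <- sub("\\.bam$", "", basename(bam))
  cls <- classify_bam(bam, models, strandedness = strandedness,
                      min_mapq = min_mapq, single_end = single_end)
  gene_ids <- models$genes$gene_id
  tab_ex <- table(factor(cls$gene_id[cls$class == "exonic"],
                         levels = gene_ids))
  tab_in <- table(factor(cls$gene_id[cls$class == "intronic"],
                         levels = gene_ids))
  counts <- data.frame(gene_id = gene_ids,
                       exonic = as.integer(tab_ex),
                       intronic = as.integer(tab_in),
                       stringsAsFactors = FALSE)
  list(counts = counts,
       library_sizes = c(exonic = sum(counts$exonic),
                         intronic = sum(counts$intronic)),
       diagnostics = list(sample_id = sample_id, n_pairs = nrow(cls),
                          n_non_unique = sum(!cls$unique),
                          n_exonic = sum(cls$class == "exonic"),
                          n_intronic = sum(cls$class == "intronic"),
                          n_unassigned = sum(cls$class == "unassigned"),
                          strandedness = strandedness,
                          min_mapq = min_mapq))
}

#' Count several alignment files into one count table
#'
#' @param bams Named character vector of BAM paths; names become sample ids.
#' @param models A `gene_models` object.
#' @param ... Passed to [count_bam()].
#' @return An [eisa_counts] object.
#' @export
count_bams <- function(bams, models, ...) {
  if (is.null(names(bams)) || any(!nzchar(names(bams))))
    names(bams) <- sub("\\.bam$", "", basename(bams))
  cols <- lapply(seq_along(bams), function(i)
    count_bam(bams[i], models, sample_id = names(bams)[i], ...))
  exonic <- sapply(cols, function(x) x$counts$exonic)
  intronic <- sapply(cols, function(x) x$counts$intronic)
  dimnames(exonic) <- dimnames(intronic) <-
    list(cols[[1]]$counts$gene_id, names(bams))
  eisa_counts(exonic, intronic,
              diagnostics = lapply(cols, `[[`, "diagnostics"))
}

#' Exon/intron count table
#'
#' Container for genes-by-samples exonic and intronic read-pair counts.
#' Library sizes are the per-class column sums.
#'
#' @param exonic,intronic Integer matrices, genes x samples, identical
#'   dimnames.
#' @param diagnostics Optional per-sample diagnostics list.
#' @return Object of class `eisa_counts`: list with `exonic`, `intronic`,
#'   `library_sizes` (2 x samples matrix, rows exonic/intronic),
#'   `diagnostics`.
#' @export
eisa_counts <- function(exonic, intronic, diagnostics = NULL) {
  exonic <- as.matrix(exonic); intronic <- as.matrix(intronic)
  stopifnot(identical(dim(exonic), dim(intronic)),
            identical(dimnames(exonic), dimnames(intronic)),
            all(exonic >= 0), all(intronic >= 0))
  if (is.null(rownames(exonic))) stop("count matrices need gene rownames")
  structure(list(
    exonic = exonic, intronic = intronic,
    library_sizes = rbind(exonic = colSums(exonic),
                          intronic = colSums(intronic)),
    diagnostics = diagnostics), class = "eisa_counts")
}

#' @export
print.eisa_counts <- function(x, ...) {
  cat("eisa_counts:", nrow(x$exonic), "genes x", ncol(x$exonic),
      "samples\n  library sizes (exonic):",
      paste(x$library_sizes["exonic", ], collapse = ", "),
      "\n  library sizes (intronic):",
      paste(x$library_sizes["intronic", ], collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an exon-intron count table as TSV
#'
#' Columns are `gene` then `<sample>.exonic` and `<sample>.intronic` per
#' sample.
#'
#' @param counts An `eisa_counts` object.
#' @param path Output (input) TSV path.
#' @return `write_counts`: invisibly `path`; `read_counts`: an
#'   `eisa_counts`.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "eisa_counts"))
  sm <- colnames(counts$exonic)
  df <- data.frame(gene = rownames(counts$exonic), check.names = FALSE)
  for (s in sm) {
    df[[paste0(s, ".exonic")]] <- counts$exonic[, s]
    df[[paste0(s, ".intronic")]] <- counts$intronic[, s]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ex_cols <- grep("\\.exonic$", names(df), value = TRUE)
  in_cols <- grep("\\.intronic$", names(df), value = TRUE)
  sm <- sub("\\.exonic$", "", ex_cols)
  stopifnot(identical(sm, sub("\\.intronic$", "", in_cols)))
  exonic <- as.matrix(df[, ex_cols, drop = FALSE])
  intronic <- as.matrix(df[, in_cols, drop = FALSE])
  dimnames(exonic) <- dimnames(intronic) <- list(df$gene, sm)
  eisa_counts(exonic, intronic)
}
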