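#' Read transcript annotation
#'
#' Parses a GTF file (Ensembl/UCSC dialects) or a RefSeq-style tab-separated
#' table into a flat exon-level `GRanges`, one range per exon, carrying
#' `gene_id` and `transcript_id` metadata columns. This is the input expected
#' by [build_gene_models()].
#'
#' Coordinates are 1-based closed internally (the R/Bioconductor convention).
#' GTF exons are read as 1-based inclusive; RefSeq-style tables follow the
#' UCSC convention of 0-based half-open `exonStarts`/`exonEnds` comma-lists
#' and are converted on input.
#'
#' @param path Path to a GTF (`.gtf`, detected by extension or `format`) or a
#'   tab-separated table with columns `gene`, `transcript`, `chrom`, `strand`,
#'   `exonStarts`, `exonEnds`.
#' @param format One of `"auto"`, `"gtf"`, `"refseq"`.
#' @return A `GRanges` of exons with metadata columns `gene_id` and
#'   `transcript_id`, sorted by transcript then start. Transcripts with zero
#'   exons are dropped with a warning.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1\tsrc\texon\t101\t200\t.\t+\t.",
#'                  'gene_id "g1"; transcript_id "t1";', sep = "\t"), gtf)
#' read_annotation(gtf)
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "refseq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "refseq"
  }
  if (format == "gtf") {
    gr <- tryCatch(
      rtracklayer::import(path, format = "gtf"),
      error = function(e) stop("failed to parse GTF '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    gr <- gr[!is.na(gr$type) & gr$type == "exon"]
    if (length(gr) == 0L) {
      warning("no exon features in ", path)
      return(empty_exon_granges())
    }
    if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
        anyNA(gr$gene_id) || anyNA(gr$transcript_id)) {
      stop("exon features in '", path, "' must carry gene_id and transcript_id")
    }
    ex <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(gr),
      ranges = IRanges::ranges(gr),
      strand = GenomicRanges::strand(gr),
      gene_id = as.character(gr$gene_id),
      transcript_id = as.character(gr$transcript_id)
    )
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
    need <- c("gene", "transcript", "chrom", "strand", "exonStarts", "exonEnds")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("RefSeq-style table '", path, "' lacks columns: ",
           paste(miss, collapse = ", "))
    parse_list <- function(x) lapply(strsplit(x, ","), function(v) as.integer(v[nzchar(v)]))
    starts <- parse_list(tab$exonStarts)
    ends <- parse_list(tab$exonEnds)
    ns <- lengths(starts)
    if (any(ns != lengths(ends)))
      stop("exonStarts/exonEnds length mismatch at table row ",
           which(ns != lengths(ends))[1])
    zero <- ns == 0L
    if (any(zero)) {
      warning(sum(zero), " transcript(s) with zero exons skipped")
      tab <- tab[!zero, , drop = FALSE]
      starts <- starts[!zero]; ends <- ends[!zero]; ns <- ns[!zero]
    }
    if (nrow(tab) == 0L) return(empty_exon_granges())
    ex <- GenomicRanges::GRanges(
      seqnames = rep(tab$chrom, ns),
      # UCSC exonStarts are 0-based half-open
      ranges = IRanges::IRanges(start = unlist(starts) + 1L, end = unlist(ends)),
      strand = rep(tab$strand, ns),
      gene_id = rep(tab$gene, ns),
      transcript_id = rep(tab$transcript, ns)
    )
  }
  ex <- ex[order(ex$transcript_id, GenomicRanges::start(ex))]
  validate_transcript_exons(ex)
  ex
}

empty_exon_granges <- function() {
  GenomicRanges::GRanges(gene_id = character(), transcript_id = character())
}

# exons within a transcript must be non-overlapping and share chrom/strand
validate_transcript_exons <- function(ex) {
  by_tx <- split(ex, ex$transcript_id)
  bad <- vapply(by_tx, function(g) {
    length(unique(as.character(GenomicRanges::seqnames(g)))) > 1L ||
      length(unique(as.character(GenomicRanges::strand(g)))) > 1L ||
      !IRanges::isDisjoint(IRanges::ranges(g))
  }, logical(1))
  if (any(bad))
    stop("transcripts with overlapping exons or mixed chrom/strand: ",
         paste(utils::head(names(by_tx)[bad], 5), collapse = ", "))
  invisible(ex)
}

#' Build gene-level exon/intron models
#'
#' Collapses exon-level annotation into one model per gene: the exonic region
#' set is the union of exons over all of the gene's transcripts and the
#' intronic region set is the gene span minus that union. Genes whose spans
#' overlap the span of any other gene on the same chromosome are excluded
#' outright, as are genes whose transcripts disagree on chromosome or strand
#' — counting then never has to disambiguate multi-gene positions.
#'
#' The 10 bp exon-proximity buffer used when classifying intronic read pairs
#' is stored on the model (`exon_buffer_bp`) and applied at classification
#' time, not subtracted from the intronic intervals themselves, so the same
#' model serves exonic and intronic queries.
#'
#' @param exons `GRanges` from [read_annotation()] (metadata `gene_id`,
#'   `transcript_id`).
#' @param overlap_mode `"any_strand"` (default; the strictest reading:
#'   overlap on either strand excludes both genes) or `"same_strand"`.
#' @param exon_buffer_bp Minimum distance (bp) an intronic read must keep
#'   from any exon; default 10.
#' @return An object of class `gene_models`: a list with
#'   \describe{
#'     \item{genes}{data.frame of retained genes: `gene_id`, `chrom`,
#'       `strand`, `start`, `end`, `tss`, `n_exons`.}
#'     \item{exonic}{named `GRangesList`, reduced exon union per gene.}
#'     \item{intronic}{named `GRangesList`, span minus exon union.}
#'     \item{excluded}{data.frame `gene_id`, `reason`.}
#'     \item{exon_buffer_bp, overlap_mode}{parameters as given.}
#'   }
#'   The TSS is the strand-aware 5'-most position of the exon union.
#' @export
build_gene_models <- function(exons,
                              overlap_mode = c("any_strand", "same_strand"),
                              exon_buffer_bp = 10L) {
  overlap_mode <- match.arg(overlap_mode)
  stopifnot(is(exons, "GRanges"), exon_buffer_bp >= 0)
  if (length(exons) == 0L) stop("no exons supplied")

  gid <- as.character(exons$gene_id)
  # mixed chrom/strand genes are excluded before span logic
  chrom_by_gene <- split(as.character(GenomicRanges::seqnames(exons)), gid)
  strand_by_gene <- split(as.character(GenomicRanges::strand(exons)), gid)
  mixed <- vapply(chrom_by_gene, function(x) length(unique(x)) > 1L, logical(1)) |
    vapply(strand_by_gene, function(x) length(unique(x)) > 1L, logical(1))
  excluded <- data.frame(gene_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (any(mixed)) {
    warning("genes with transcripts on mixed chrom/strand excluded: ",
            paste(utils::head(names(mixed)[mixed], 5), collapse = ", "))
    excluded <- rbind(excluded, data.frame(
      gene_id = names(mixed)[mixed], reason = "mixed_chrom_or_strand",
      stringsAsFactors = FALSE))
    exons <- exons[!gid %in% names(mixed)[mixed]]
    gid <- as.character(exons$gene_id)
  }
  if (length(exons) == 0L) stop("all genes excluded (mixed chrom/strand)")

  # gene spans, sorted deterministically by gene_id
  spans <- unlist(range(GenomicRanges::split(exons, gid)))
  spans <- spans[order(names(spans))]
  ignore_strand <- overlap_mode == "any_strand"
  hits <- GenomicRanges::findOverlaps(spans, spans,
                                      ignore.strand = ignore_strand)
  hits <- hits[S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
  overlapping <- sort(unique(names(spans)[S4Vectors::queryHits(hits)]))
  if (length(overlapping)) {
    excluded <- rbind(excluded, data.frame(
      gene_id = overlapping, reason = "overlaps_another_gene",
      stringsAsFactors = FALSE))
  }
  keep <- setdiff(names(spans), overlapping)
  if (length(keep) == 0L) stop("no non-overlapping genes remain")
  spans <- spans[keep]

  exons_keep <- exons[gid %in% keep]
  exonic <- GenomicRanges::reduce(
    GenomicRanges::split(exons_keep, as.character(exons_keep$gene_id)))
  exonic <- exonic[keep]
  intronic <- GenomicRanges::psetdiff(spans, exonic)

  st <- as.character(GenomicRanges::strand(spans))
  genes <- data.frame(
    gene_id = keep,
    chrom = as.character(GenomicRanges::seqnames(spans)),
    strand = st,
    start = GenomicRanges::start(spans),
    end = GenomicRanges::end(spans),
    tss = ifelse(st == "-", GenomicRanges::end(spans),
                 GenomicRanges::start(spans)),
    n_exons = lengths(exonic),
    stringsAsFactors = FALSE, row.names = NULL
  )
  excluded <- excluded[order(excluded$gene_id), , drop = FALSE]
  row.names(excluded) <- NULL
  structure(list(genes = genes, exonic = exonic, intronic = intronic,
                 excluded = excluded,
                 exon_buffer_bp = as.integer(exon_buffer_bp),
                 overlap_mode = overlap_mode),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes retained,",
      nrow(x$excluded), "excluded;",
      "exon buffer", x$exon_buffer_bp, "bp;",
      "overlap mode", x$overlap_mode, "\n")
  invisible(x)
}

#' Dump gene models and exclusions to disk
#'
#' Writes a BED12-like inspection table (one line per gene with exon block
#' structure) and, optionally, a TSV of excluded genes with the exclusion
#' reason.
#'
#' @param models A `gene_models` object.
#' @param bed_path Output path for the BED12-like dump (0-based half-open,
#'   as BED requires).
#' @param excluded_path Optional path for the exclusion TSV.
#' @return Invisibly, `bed_path`.
#' @export
write_gene_models <- function(models, bed_path, excluded_path = NULL) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  ex <- models$exonic[g$gene_id]
  starts <- GenomicRanges::start(ex)
  widths <- GenomicRanges::width(ex)
  block_starts <- vapply(seq_along(ex), function(i)
    paste(starts[[i]] - g$start[i], collapse = ","), character(1))
  block_sizes <- vapply(widths, paste, character(1), collapse = ",")
  bed <- data.frame(
    chrom = g$chrom, start = g$start - 1L, end = g$end,
    name = g$gene_id, score = 0L, strand = g$strand,
    thickStart = g$start - 1L, thickEnd = g$end, rgb = "0,0,0",
    blockCount = lengths(ex), blockSizes = block_sizes,
    blockStarts = block_starts, stringsAsFactors = FALSE)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(excluded_path)) {
    utils::write.table(models$excluded, excluded_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(bed_path)
}

#' Per-gene transcription start sites
#'
#' @param models A `gene_models` object.
#' @return data.frame `gene_id`, `chrom`, `strand`, `tss` (1-based, the
#'   strand-aware 5'-most base of the exon union).
#' @export
gene_tss <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  models$genes[, c("gene_id", "chrom", "strand", "tss")]
}
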