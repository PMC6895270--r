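#' Read a differential peak table
#'
#' MAnorm-style normalized differential ChIP-seq peaks: tab-separated with
#' columns `chrom`, `start`, `end` (1-based closed), `M` (log2 fold-change
#' of the mark between conditions) and `A` (average intensity); an optional
#' `mark` column labels the modification.
#'
#' @param path TSV path.
#' @return data.frame of peaks; `M` and `A` must be finite.
#' @export
read_diff_peaks <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chrom", "start", "end", "M", "A")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$M)) || any(!is.finite(df$A)))
    stop("non-finite M or A values in ", path)
  if (any(df$end < df$start)) stop("malformed peak interval in ", path)
  df
}

#' Assign promoter M-values to genes
#'
#' Converts a peak-centric differential table to a gene-centric one: the
#' promoter is the window `promoter_halfwidth` bp up- and down-stream of
#' the strand-aware TSS; a gene with no overlapping peak gets `M_gene = 0`;
#' with exactly one peak, that peak's M; with two or more, the M of the
#' largest peak, i.e. the one with the greatest A-value (equal A: the
#' leftmost peak wins, so assignment is deterministic and independent of
#' peak input order).
#'
#' @param peaks data.frame from [read_diff_peaks()] (one mark).
#' @param tss data.frame from [gene_tss()] (`gene_id`, `chrom`, `strand`,
#'   `tss`).
#' @param promoter_halfwidth Half-width of the promoter window in bp;
#'   default 1000 (a 2 kb window).
#' @return data.frame `gene_id`, `M_gene`, `n_overlapping_peaks`.
#' @export
assign_gene_m <- function(peaks, tss, promoter_halfwidth = 1000L) {
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(tss)))
  bad <- is.na(tss$tss)
  if (any(bad)) {
    warning("genes without TSS skipped: ",
            paste(utils::head(tss$gene_id[bad], 5), collapse = ", "))
    tss <- tss[!bad, , drop = FALSE]
  }
  prom <- GenomicRanges::GRanges(
    tss$chrom,
    IRanges::IRanges(start = pmax(1L, tss$tss - promoter_halfwidth),
                     end = tss$tss + promoter_halfwidth - 1L))
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start, peaks$end))
  GenomeInfoDb::seqlevels(pk) <- union(GenomeInfoDb::seqlevels(pk),
                                       GenomeInfoDb::seqlevels(prom))
  hits <- GenomicRanges::findOverlaps(prom, pk, ignore.strand = TRUE)
  M_gene <- numeric(nrow(tss))
  n_pk <- integer(nrow(tss))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    # winner per gene: greatest A, ties broken by leftmost start
    ord <- order(qh, -peaks$A[sh], peaks$start[sh])
    qh <- qh[ord]; sh <- sh[ord]
    n_tab <- table(factor(qh, levels = seq_len(nrow(tss))))
    n_pk <- as.integer(n_tab)
    first <- !duplicated(qh)
    M_gene[qh[first]] <- peaks$M[sh[first]]
  }
  data.frame(gene_id = tss$gene_id, M_gene = M_gene,
             n_overlapping_peaks = n_pk, stringsAsFactors = FALSE)
}

#' Sliding-window means over ranked genes
#'
#' Given per-gene values already ordered by the rank of interest, computes
#' the mean in consecutive rank blocks of size `window`, advanced by `step`
#' genes — the smoothing used to display chromatin-mark enrichment along a
#' regulation ranking. With `n` genes the profile has
#' `floor((n - window)/step) + 1` windows.
#'
#' @param values Numeric vector in rank order.
#' @param window Window size in genes; default 25.
#' @param step Advance between plotted windows; default 5.
#' @return data.frame `window` (index), `start_rank`, `end_rank`, `mean`.
#'   If `length(values) < window`, a single window over all genes is
#'   returned with a warning.
#' @export
sliding_window_profile <- function(values, window = 25L, step = 5L) {
  n <- length(values)
  stopifnot(window >= 1L, step >= 1L)
  if (n < window) {
    warning("fewer genes (", n, ") than window (", window,
            "): single window over all genes")
    return(data.frame(window = 1L, start_rank = 1L, end_rank = n,
                      mean = mean(values)))
  }
  starts <- seq.int(1L, n - window + 1L, by = step)
  data.frame(
    window = seq_along(starts),
    start_rank = starts,
    end_rank = starts + window - 1L,
    mean = vapply(starts, function(s) mean(values[s:(s + window - 1L)]),
                  numeric(1)))
}

#' Concordance between transcriptional change and promoter mark change
#'
#' Spearman rank correlation, per mark, between a gene's intronic
#' fold-change (`dI`, the transcription proxy) and its promoter M-value
#' over a selected gene set (typically the top up/down-regulated genes from
#' [rank_select()]). Active marks are expected to correlate positively,
#' repressive marks negatively.
#'
#' @param result An `eisa_result`.
#' @param gene_m Named list of [assign_gene_m()] outputs, one per mark.
#' @param genes Character vector of selected gene ids.
#' @param min_genes Minimum selected genes with at least one overlapping
#'   peak; below this the correlation is `NA`. Default 10.
#' @return data.frame `mark`, `rho`, `n_with_peaks`.
#' @export
concordance_report <- function(result, gene_m, genes, min_genes = 10L) {
  stopifnot(is.list(gene_m), !is.null(names(gene_m)))
  df <- as.data.frame(result)
  rows <- lapply(names(gene_m), function(mark) {
    gm <- gene_m[[mark]]
    idx <- match(genes, gm$gene_id)
    sel <- !is.na(idx) & gm$n_overlapping_peaks[idx] > 0
    n_pk <- sum(sel)
    rho <- NA_real_
    if (n_pk >= min_genes) {
      di <- df$dI[match(genes[sel], df$gene_id)]
      m <- gm$M_gene[idx[sel]]
      if (stats::sd(m) > 0 && stats::sd(di) > 0)
        rho <- stats::cor(di, m, method = "spearman")
    }
    data.frame(mark = mark, rho = rho, n_with_peaks = n_pk,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
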