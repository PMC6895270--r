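#' Normalize and filter an exon-intron count table
#'
#' Exonic and intronic counts are library-size normalized independently
#' within each class, using TMM effective library sizes (trimmed mean of
#' M-values) so that strongly regulated genes do not drag the scaling of
#' the unregulated majority, then transformed to
#' `log2(scaled + pseudocount)`. Genes are retained only if their mean
#' normalized log2 abundance reaches `min_expr` in *both* classes —
#' intronic coverage is almost always the limiting class.
#'
#' @param counts An [eisa_counts] object.
#' @param design Character or factor of condition labels, one per sample
#'   (exactly two levels for downstream contrasts).
#' @param min_expr Minimum mean normalized log2 abundance per class;
#'   default `log2(16)`.
#' @param pseudocount Added before the log; default 8.
#' @return List with `log_exonic`, `log_intronic` (genes x samples log2
#'   matrices over all genes), `retained` (character vector of gene ids
#'   passing the filter) and `params`.
#' @export
normalize_and_filter <- function(counts, design, min_expr = log2(16),
                                 pseudocount = 8) {
  stopifnot(inherits(counts, "eisa_counts"))
  design <- as.factor(design)
  if (length(design) != ncol(counts$exonic))
    stop("design length (", length(design), ") != number of samples (",
         ncol(counts$exonic), ")")
  if (any(table(design) < 1L)) stop("every condition needs >= 1 sample")
  norm_class <- function(mat) {
    lib <- colSums(mat)
    if (any(lib == 0))
      stop("zero total counts in sample(s): ",
           paste(colnames(mat)[lib == 0], collapse = ", "))
    eff <- lib * edgeR::calcNormFactors(mat, lib.size = lib,
                                        method = "TMM")
    scaled <- sweep(mat, 2, eff, "/") * mean(eff)
    log2(scaled + pseudocount)
  }
  log_ex <- norm_class(counts$exonic)
  log_in <- norm_class(counts$intronic)
  retained <- rownames(log_ex)[rowMeans(log_ex) >= min_expr &
                               rowMeans(log_in) >= min_expr]
  list(log_exonic = log_ex, log_intronic = log_in, retained = retained,
       params = list(min_expr = min_expr, pseudocount = pseudocount,
                     design = design))
}

#' Point estimates of dE, dI and dE - dI
#'
#' Average normalized log2 abundance difference between the two conditions
#' (second level minus first level of `design`), per class. `dI` tracks the
#' change in transcription (pre-mRNA); `dE - dI` (`dEmI`) the
#' post-transcriptional change in mRNA stability.
#'
#' @param norm Output of [normalize_and_filter()].
#' @param design Condition labels (two levels); defaults to the design
#'   stored in `norm`.
#' @return data.frame `gene_id`, `dE`, `dI`, `dEmI`, `mean_expr_exonic`,
#'   `mean_expr_intronic` over the retained genes.
#' @export
compute_deltas <- function(norm, design = norm$params$design) {
  design <- as.factor(design)
  lv <- levels(design)
  if (length(lv) != 2L) stop("exactly two conditions required, got: ",
                             paste(lv, collapse = ", "))
  keep <- norm$retained
  le <- norm$log_exonic[keep, , drop = FALSE]
  li <- norm$log_intronic[keep, , drop = FALSE]
  d <- function(m) rowMeans(m[, design == lv[2], drop = FALSE]) -
    rowMeans(m[, design == lv[1], drop = FALSE])
  dE <- d(le); dI <- d(li)
  data.frame(gene_id = keep, dE = dE, dI = dI, dEmI = dE - dI,
             mean_expr_exonic = rowMeans(le),
             mean_expr_intronic = rowMeans(li),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Moderated significance tests for dI and dE - dI
#'
#' The transcriptional component (`dI`) is tested as a two-group contrast on
#' the intronic counts; the post-transcriptional component (`dEmI`) as the
#' condition-by-class interaction on the paired exonic/intronic counts.
#' Both use negative-binomial models with empirical-Bayes shrunken tagwise
#' dispersions and quasi-likelihood F-tests (edgeR), with library sizes
#' taken per class so normalization stays independent between classes.
#' Benjamini-Hochberg FDR is computed within each component.
#'
#' @param counts An [eisa_counts] object.
#' @param design Condition labels (two levels, >= 2 replicates each for
#'   dispersion estimation; with fewer replicates p-values are returned as
#'   `NA`).
#' @param genes Genes to test (default: all rows).
#' @param include_dE Also test the exonic two-group contrast (the plain
#'   RNA-seq comparison, used by the depth titration); default `FALSE`.
#' @return data.frame `gene_id`, `p_dI`, `fdr_dI`, `p_dEmI`, `fdr_dEmI`
#'   (plus `p_dE`, `fdr_dE` when `include_dE`).
#' @export
test_significance <- function(counts, design,
                              genes = rownames(counts$exonic),
                              include_dE = FALSE) {
  stopifnot(inherits(counts, "eisa_counts"))
  design <- as.factor(design)
  lv <- levels(design)
  if (length(lv) != 2L) stop("exactly two conditions required")
  if (any(table(design) < 2L)) {
    warning("fewer than 2 replicates per condition: p-values undefined")
    out <- data.frame(gene_id = genes, p_dI = NA_real_, fdr_dI = NA_real_,
                      p_dEmI = NA_real_, fdr_dEmI = NA_real_,
                      stringsAsFactors = FALSE)
    if (include_dE) out$p_dE <- out$fdr_dE <- NA_real_
    return(out)
  }
  ex <- counts$exonic[genes, , drop = FALSE]
  intr <- counts$intronic[genes, , drop = FALSE]
  mm <- stats::model.matrix(~design)

  # TMM effective library sizes, from the full (unfiltered) class matrix
  # so normalization matches normalize_and_filter()
  eff_lib <- function(mat) {
    lib <- colSums(mat)
    lib * edgeR::calcNormFactors(mat, lib.size = lib, method = "TMM")
  }
  lib_ex <- eff_lib(counts$exonic)
  lib_in <- eff_lib(counts$intronic)

  # two-group NB quasi-likelihood test within one read class
  two_group_p <- function(mat, lib) {
    y <- edgeR::DGEList(counts = mat, lib.size = lib, group = design)
    y <- edgeR::estimateDisp(y, mm)
    fit <- edgeR::glmQLFit(y, mm)
    edgeR::glmQLFTest(fit, coef = 2)$table$PValue
  }
  p_dI <- two_group_p(intr, lib_in)

  # dEmI: condition x class interaction on the paired count matrix;
  # exonic and intronic columns of a sample are modelled as separate
  # libraries with their own (class-wise) library sizes
  comb <- cbind(ex, intr)
  colnames(comb) <- c(paste0(colnames(ex), ".exonic"),
                      paste0(colnames(intr), ".intronic"))
  # exonic columns come first in comb; intronic is the reference class
  cls <- factor(rep(c("exonic", "intronic"), each = ncol(ex)),
                levels = c("intronic", "exonic"))
  cond <- factor(rep(design, 2), levels = lv)
  libs <- c(lib_ex, lib_in)
  mm2 <- stats::model.matrix(~cls + cond + cls:cond)
  y_c <- edgeR::DGEList(counts = comb, lib.size = libs)
  y_c <- edgeR::estimateDisp(y_c, mm2)
  fit_c <- edgeR::glmQLFit(y_c, mm2)
  res_c <- edgeR::glmQLFTest(fit_c, coef = ncol(mm2))
  p_dEmI <- res_c$table$PValue

  out <- data.frame(gene_id = genes,
                    p_dI = p_dI, fdr_dI = stats::p.adjust(p_dI, "BH"),
                    p_dEmI = p_dEmI,
                    fdr_dEmI = stats::p.adjust(p_dEmI, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (include_dE) {
    p_dE <- two_group_p(ex, lib_ex)
    out$p_dE <- p_dE
    out$fdr_dE <- stats::p.adjust(p_dE, "BH")
  }
  out
}

#' Run the full split analysis on a count table
#'
#' Normalization/filtering, dE/dI/dEmI point estimates and component-wise
#' significance tests in one call.
#'
#' @inheritParams normalize_and_filter
#' @param test Compute p-values (default `TRUE`); set `FALSE` for point
#'   estimates only (e.g. inside tight simulation loops).
#' @return An `eisa_result` data.frame with columns `gene_id`, `dE`, `dI`,
#'   `dEmI`, `p_dI`, `fdr_dI`, `p_dEmI`, `fdr_dEmI`, `mean_expr_exonic`,
#'   `mean_expr_intronic`.
#' @export
eisa <- function(counts, design, min_expr = log2(16), pseudocount = 8,
                 test = TRUE) {
  norm <- normalize_and_filter(counts, design, min_expr, pseudocount)
  if (length(norm$retained) == 0L)
    stop("no genes pass the expression filter (min_expr = ", min_expr, ")")
  res <- compute_deltas(norm, design)
  if (test) {
    sig <- test_significance(counts, design, genes = norm$retained)
    res <- merge(res, sig, by = "gene_id", sort = FALSE)
  } else {
    res$p_dI <- res$fdr_dI <- res$p_dEmI <- res$fdr_dEmI <- NA_real_
  }
  res <- res[order(res$gene_id),
             c("gene_id", "dE", "dI", "dEmI", "p_dI", "fdr_dI",
               "p_dEmI", "fdr_dEmI", "mean_expr_exonic",
               "mean_expr_intronic")]
  row.names(res) <- NULL
  class(res) <- c("eisa_result", "data.frame")
  res
}

#' Relative transcriptional vs post-transcriptional contribution
#'
#' Places each gene on the axes (x, y) = (dI, dE - dI), keeps the
#' differentially expressed genes — those with `|x + y| > threshold`
#' (note x + y = dE); set `signed = TRUE` for the one-sided reading
#' `x + y > threshold` — and reports the fraction whose absolute
#' transcriptional change exceeds the absolute post-transcriptional change
#' (and vice versa). Exact ties are tallied separately.
#'
#' @param result An `eisa_result` (or any data.frame with `dI`, `dEmI`).
#' @param threshold Log2 differential-expression threshold; default 1.
#' @param signed Use the one-sided threshold on x + y; default `FALSE`.
#' @return Object of class `contribution_summary`: list with
#'   `n_considered`, `frac_transcriptional`, `frac_posttranscriptional`,
#'   `n_ties`, `threshold`. Fractions are `NA` when no gene passes.
#' @export
contribution_metric <- function(result, threshold = 1, signed = FALSE) {
  x <- result$dI; y <- result$dEmI
  s <- x + y
  considered <- if (signed) s > threshold else abs(s) > threshold
  n <- sum(considered)
  if (n == 0L) {
    out <- list(n_considered = 0L, frac_transcriptional = NA_real_,
                frac_posttranscriptional = NA_real_, n_ties = 0L,
                threshold = threshold)
    return(structure(out, class = "contribution_summary"))
  }
  ax <- abs(x[considered]); ay <- abs(y[considered])
  structure(list(
    n_considered = n,
    frac_transcriptional = sum(ax > ay) / n,
    frac_posttranscriptional = sum(ay > ax) / n,
    n_ties = sum(ax == ay),
    threshold = threshold), class = "contribution_summary")
}

#' @export
print.contribution_summary <- function(x, ...) {
  cat("contribution_summary:", x$n_considered,
      "genes with |dE| >", x$threshold, "\n",
      " transcriptional:", round(x$frac_transcriptional, 3),
      " post-transcriptional:", round(x$frac_posttranscriptional, 3),
      " ties:", x$n_ties, "\n")
  invisible(x)
}

#' Deterministic top-gene selection
#'
#' Selects the top `n` (or top `fraction`) genes by a result column, either
#' most positive (`"up"`), most negative (`"down"`) or largest in absolute
#' value (`"abs"`). Ties are broken lexicographically by `gene_id` so the
#' selection is reproducible.
#'
#' @param result An `eisa_result` (or compatible data.frame). Pre-subset
#'   the rows to impose side conditions (e.g. `abs(dI) < 0.5`).
#' @param key Column to rank by: `"dI"`, `"dEmI"` or `"dE"`.
#' @param direction `"up"`, `"down"` or `"abs"`.
#' @param n Number of genes; if `NULL`, use `fraction`.
#' @param fraction Top fraction of genes (e.g. `0.05`); rounded down, at
#'   least 1.
#' @return Character vector of selected gene ids, in rank order.
#' @export
rank_select <- function(result, key = c("dI", "dEmI", "dE"),
                        direction = c("up", "down", "abs"),
                        n = NULL, fraction = NULL) {
  key <- match.arg(key)
  direction <- match.arg(direction)
  if (is.null(n) && is.null(fraction)) stop("give n or fraction")
  m <- nrow(result)
  if (is.null(n)) n <- max(1L, floor(fraction * m))
  if (n > m) {
    warning("n = ", n, " > ", m, " genes; returning all")
    n <- m
  }
  v <- result[[key]]
  score <- switch(direction, up = -v, down = v, abs = -abs(v))
  ord <- order(score, result$gene_id)
  result$gene_id[ord[seq_len(n)]]
}

#' Write an EISA result table as TSV
#'
#' @param result An `eisa_result`.
#' @param path Output path.
#' @param header Optional character vector of `# `-prefixed provenance
#'   comment lines written before the table.
#' @return Invisibly, `path`.
#' @export
write_eisa_result <- function(result, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(result, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_eisa_result
#' @export
read_eisa_result <- function(path) {
  res <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  class(res) <- c("eisa_result", "data.frame")
  res
}
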