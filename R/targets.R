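#' Read miRNA target predictions
#'
#' Consumes a TargetScan-style TSV with columns `gene`, `site_count`,
#' `best_site_type` (`6mer`, `7mer`, `8mer` or `none`), `rank` (1 =
#' strongest prediction) and optionally `predictor`.
#'
#' @param path TSV path.
#' @return data.frame with those columns (predictor defaults to
#'   `"predictor1"`), plus `site_count_class` (`"0"`, `"1"`, `"2"`, `"3+"`).
#' @export
read_target_predictions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene", "site_count", "best_site_type", "rank")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("prediction table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(df$predictor)) df$predictor <- "predictor1"
  df$site_count_class <- site_count_class(df$site_count)
  bad <- df$site_count == 0 & df$best_site_type != "none"
  if (any(bad)) stop("site_count 0 must have best_site_type 'none'")
  df
}

site_count_class <- function(n) {
  factor(ifelse(n >= 3, "3+", as.character(pmin(n, 3))),
         levels = c("0", "1", "2", "3+"))
}

#' Stratified empirical CDFs of a regulation metric
#'
#' Joins an EISA result with target-site annotation and returns the values
#' of the chosen metric per site-count stratum (0, 1, 2, 3+ predicted
#' sites), ready for cumulative-distribution plotting and K-S testing.
#' Genes absent from the annotation are treated as having no sites.
#'
#' When `metric = "dI"` the gene universe is first restricted to genes with
#' `|dEmI| < dI_control_cutoff` (default 0.5) — the transcription-only
#' control: if sites act on mRNA stability, no ordered shift should remain
#' in these strata.
#'
#' @param result An `eisa_result`.
#' @param targets Prediction data.frame from [read_target_predictions()]
#'   (one predictor).
#' @param metric `"dEmI"`, `"dE"` or `"dI"`.
#' @param dI_control_cutoff Universe restriction used for `metric = "dI"`.
#' @param by Stratify by `"count"` (default) or by `"type"` (none/6mer/
#'   7mer/8mer, strongest site).
#' @param min_stratum Strata smaller than this are kept but flagged with a
#'   warning; default 10.
#' @return Object of class `cdf_strata`: list with `strata` (named list of
#'   metric values), `metric`, `means`, `n`, `small` (logical flags).
#' @export
stratified_cdf <- function(result, targets,
                           metric = c("dEmI", "dE", "dI"),
                           dI_control_cutoff = 0.5,
                           by = c("count", "type"), min_stratum = 10L) {
  metric <- match.arg(metric)
  by <- match.arg(by)
  df <- as.data.frame(result)
  if (metric == "dI") df <- df[abs(df$dEmI) < dI_control_cutoff, ,
                               drop = FALSE]
  idx <- match(df$gene_id, targets$gene)
  if (by == "count") {
    lab <- site_count_class(ifelse(is.na(idx), 0L,
                                   targets$site_count[idx]))
  } else {
    ty <- ifelse(is.na(idx), "none", targets$best_site_type[idx])
    lab <- factor(ty, levels = c("none", "6mer", "7mer", "8mer"))
  }
  strata <- split(df[[metric]], lab)
  if (all(lengths(strata) == 0L)) stop("no genes in any stratum")
  small <- lengths(strata) < min_stratum
  if (any(small))
    warning("strata below ", min_stratum, " genes: ",
            paste(names(strata)[small], collapse = ", "))
  structure(list(strata = strata, metric = metric,
                 means = vapply(strata, function(v)
                   if (length(v)) mean(v) else NA_real_, numeric(1)),
                 n = lengths(strata), small = small),
            class = "cdf_strata")
}

#' @export
print.cdf_strata <- function(x, ...) {
  cat("cdf_strata on", x$metric, "\n")
  print(data.frame(stratum = names(x$strata), n = x$n,
                   mean = round(x$means, 3), row.names = NULL))
  invisible(x)
}

#' Pairwise two-sample Kolmogorov-Smirnov tests between strata
#'
#' All-vs-all two-sided K-S tests on the stratified metric values. The
#' exact p-value is used when both strata have fewer than 30 genes,
#' the asymptotic one otherwise. Pairs involving a stratum of fewer than
#' two values are skipped (`NA`).
#'
#' @param strata A `cdf_strata` object or a named list of numeric vectors.
#' @return List with matrices `D` (K-S statistics) and `p` (p-values),
#'   strata in rows/columns.
#' @export
pairwise_ks <- function(strata) {
  if (inherits(strata, "cdf_strata")) strata <- strata$strata
  k <- length(strata)
  if (k < 2L) stop("need >= 2 strata")
  nm <- names(strata)
  D <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        if (length(strata[[i]]) >= 2L) { D[i, j] <- 0; p[i, j] <- 1 }
        next
      }
      a <- strata[[i]]; b <- strata[[j]]
      if (length(a) < 2L || length(b) < 2L) next
      exact <- length(a) < 30L && length(b) < 30L
      kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
      D[i, j] <- unname(kt$statistic)
      p[i, j] <- kt$p.value
    }
  }
  list(D = D, p = p)
}

#' Select putative direct miRNA targets
#'
#' Intersects (i) the `n` genes with the most negative post-transcriptional
#' change (signed `dEmI`) with (ii) the `n` strongest predicted targets
#' (best prediction rank per gene, combined across predictors by union or
#' intersection).
#'
#' @param result An `eisa_result`.
#' @param targets Prediction data.frame (possibly several predictors,
#'   distinguished by the `predictor` column); rows with `site_count` 0 are
#'   ignored.
#' @param n Size of each top list; default 1000.
#' @param combine `"union"` (a gene qualifies if in the top `n` of any
#'   predictor; default) or `"intersection"` (all predictors).
#' @return Character vector of gene ids (sorted), the putative direct
#'   targets. Length is at most `n` and monotone non-decreasing in `n`.
#' @export
select_direct_targets <- function(result, targets, n = 1000L,
                                  combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  targets <- targets[targets$site_count > 0, , drop = FALSE]
  down <- rank_select(result, key = "dEmI", direction = "down", n = n)
  by_pred <- split(targets, targets$predictor)
  top_pred <- lapply(by_pred, function(tp) {
    if (nrow(tp) < n)
      warning("predictor ", tp$predictor[1], " has only ", nrow(tp),
              " predicted genes (< n = ", n, "); using all")
    tp$gene[order(tp$rank, tp$gene)][seq_len(min(n, nrow(tp)))]
  })
  predicted <- if (combine == "union") Reduce(union, top_pred)
               else Reduce(intersect, top_pred)
  sort(intersect(down, predicted))
}
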