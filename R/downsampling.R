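#' Thin a count vector to a target depth
#'
#' Multivariate-hypergeometric thinning: draws `target` read pairs without
#' replacement from the pool implied by the counts, so the thinned vector
#' sums exactly to `target` and each cell's expectation is
#' `x * target / sum(x)`. Equivalent to uniform subsampling of the
#' underlying read pairs.
#'
#' @param x Non-negative integer vector of counts.
#' @param target Target total; must not exceed `sum(x)`.
#' @return Integer vector like `x` summing to `target`. Deterministic under
#'   `set.seed()`.
#' @export
downsample_counts <- function(x, target) {
  total <- sum(x)
  if (target > total)
    stop("target depth ", target, " exceeds current depth ", total)
  if (target == total) return(x)
  picked <- sample.int(total, target)
  y <- tabulate(findInterval(picked, cumsum(x), left.open = TRUE) + 1L,
                nbins = length(x))
  storage.mode(y) <- storage.mode(x)
  names(y) <- names(x)
  y
}

#' Thin every sample of a count table to a target read-pair depth
#'
#' Exonic and intronic counts of a sample are thinned jointly (one
#' hypergeometric draw over all gene-by-class cells), mimicking uniform
#' subsampling of that sample's read pairs, so the realized intron-mapping
#' fraction stays unbiased.
#'
#' @param counts An [eisa_counts] object.
#' @param target_depth Target total read pairs per sample (scalar or one
#'   per sample).
#' @return A thinned `eisa_counts` object.
#' @export
downsample <- function(counts, target_depth) {
  stopifnot(inherits(counts, "eisa_counts"))
  ns <- ncol(counts$exonic)
  target_depth <- rep_len(target_depth, ns)
  ex <- counts$exonic; intr <- counts$intronic
  for (s in seq_len(ns)) {
    joint <- c(ex[, s], intr[, s])
    thin <- downsample_counts(joint, target_depth[s])
    ng <- nrow(ex)
    ex[, s] <- thin[seq_len(ng)]
    intr[, s] <- thin[ng + seq_len(ng)]
  }
  eisa_counts(ex, intr)
}

#' Depth titration of split-analysis power
#'
#' Reruns the full analysis (normalize, filter, estimate, test) after
#' thinning every sample to each rung of a depth ladder and records how
#' many genes stay significant per component, alongside the realized
#' intron-mapping fraction — the depth-requirement analysis. The default
#' ladder mirrors the seven study depths at a configurable scale.
#'
#' @param counts An [eisa_counts] object (full depth).
#' @param design Condition labels (two levels).
#' @param depths Target read-pair totals per sample, strictly decreasing.
#'   Default: `c(60, 50, 40, 30, 20, 10, 5) * 1e6 * depth_scale`.
#' @param depth_scale Scale applied to the default ladder; default `1e-3`
#'   (60k down to 5k pairs), sized for synthetic cohorts.
#' @param alpha FDR cutoff defining "significant"; default 0.05.
#' @param min_expr,pseudocount Passed to [eisa()].
#' @param filter_at `"each_depth"` (default): the expression filter is
#'   re-applied after thinning, so the analysis at each rung is exactly
#'   the analysis a lab would run at that depth. `"full_depth"`: the gene
#'   universe is fixed by filtering at full depth and reused at every
#'   rung; use this to compare the saturation of the *tests* across
#'   depths without the (intron-limited) filter re-selecting genes at
#'   every rung.
#' @return Object of class `depth_titration`: data.frame `depth`,
#'   `intron_fraction`, `n_retained`, `n_sig_dI`, `n_sig_dEmI`, `n_sig_dE`
#'   (the exonic-only, plain RNA-seq comparison, for saturation
#'   contrasts). Depths exceeding any sample's current depth are skipped
#'   with a warning.
#' @export
titrate <- function(counts, design,
                    depths = NULL, depth_scale = 1e-3, alpha = 0.05,
                    min_expr = log2(16), pseudocount = 8,
                    filter_at = c("each_depth", "full_depth")) {
  stopifnot(inherits(counts, "eisa_counts"))
  filter_at <- match.arg(filter_at)
  universe <- if (filter_at == "full_depth")
    normalize_and_filter(counts, design, min_expr, pseudocount)$retained
  else NULL
  if (is.null(depths))
    depths <- as.integer(c(60, 50, 40, 30, 20, 10, 5) * 1e6 * depth_scale)
  depths <- sort(unique(as.integer(depths)), decreasing = TRUE)
  cur <- colSums(counts$library_sizes)
  feasible <- depths <= min(cur)
  if (any(!feasible))
    warning("skipping depths above the shallowest sample (",
            min(cur), "): ", paste(depths[!feasible], collapse = ", "))
  rows <- lapply(depths[feasible], function(d) {
    thin <- downsample(counts, d)
    ifrac <- sum(thin$library_sizes["intronic", ]) /
      sum(thin$library_sizes)
    retained <- if (is.null(universe))
      normalize_and_filter(thin, design, min_expr, pseudocount)$retained
    else universe
    if (length(retained) == 0L)
      return(data.frame(depth = d, intron_fraction = ifrac,
                        n_retained = 0L, n_sig_dI = 0L, n_sig_dEmI = 0L,
                        n_sig_dE = 0L))
    sig <- test_significance(thin, design, genes = retained,
                             include_dE = TRUE)
    data.frame(
      depth = d, intron_fraction = ifrac,
      n_retained = length(retained),
      n_sig_dI = sum(sig$fdr_dI < alpha, na.rm = TRUE),
      n_sig_dEmI = sum(sig$fdr_dEmI < alpha, na.rm = TRUE),
      n_sig_dE = sum(sig$fdr_dE < alpha, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("depth_titration", "data.frame")
  out
}
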