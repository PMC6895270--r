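test_that("promoter M-value assignment follows the 0/1/largest-A rules", {
  tss <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    chrom = "chr1", strand = "+",
                    tss = c(5000, 15000, 25000, 35000))
  peaks <- data.frame(
    chrom = "chr1",
    start = c(14800, 24500, 25200, 34900, 35100),
    end = c(15050, 24900, 25600, 35000, 35300),
    M = c(1.7, 2.0, -1.0, 0.5, 0.9),
    A = c(4.2, 5.0, 9.0, 7.0, 7.0))
  gm <- assign_gene_m(peaks, tss)
  expect_equal(gm$M_gene[gm$gene_id == "g1"], 0)      # no peak
  expect_equal(gm$n_overlapping_peaks[gm$gene_id == "g1"], 0)
  expect_equal(gm$M_gene[gm$gene_id == "g2"], 1.7)    # single peak
  expect_equal(gm$M_gene[gm$gene_id == "g3"], -1.0)   # greatest A wins
  expect_equal(gm$n_overlapping_peaks[gm$gene_id == "g3"], 2)
  expect_equal(gm$M_gene[gm$gene_id == "g4"], 0.5)    # equal A: leftmost
})

test_that("assignment is bit-exact against a brute-force oracle and
           independent of peak order", {
  set.seed(8)
  n <- 50
  tss <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
                    strand = rep(c("+", "-"), length.out = n),
                    tss = seq(10000, by = 5000, length.out = n))
  # 0, 1 or 2 peaks per promoter
  n_pk <- sample(0:2, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  rows <- list()
  for (i in seq_len(n)) {
    if (n_pk[i] == 0) next
    for (j in seq_len(n_pk[i])) {
      s <- tss$tss[i] + sample(-900:500, 1)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = "chr1", start = s, end = s + sample(100:300, 1),
        M = round(rnorm(1), 3), A = round(runif(1, 1, 10), 3))
    }
  }
  peaks <- do.call(rbind, rows)
  hw <- 1000L
  gm <- assign_gene_m(peaks, tss, promoter_halfwidth = hw)
  # independent re-derivation: explicit loop over genes and peaks
  for (i in seq_len(n)) {
    lo <- tss$tss[i] - hw; hi <- tss$tss[i] + hw - 1L
    ov <- peaks[peaks$end >= lo & peaks$start <= hi, , drop = FALSE]
    expected <- if (nrow(ov) == 0) 0 else {
      ov <- ov[order(-ov$A, ov$start), , drop = FALSE]
      ov$M[1]
    }
    expect_identical(gm$M_gene[i], expected)
    expect_identical(gm$n_overlapping_peaks[i], nrow(ov))
  }
  set.seed(9)
  gm2 <- assign_gene_m(peaks[sample(nrow(peaks)), ], tss,
                       promoter_halfwidth = hw)
  expect_identical(gm, gm2)
})

test_that("sliding-window profiles have the documented window count", {
  v <- seq_len(100)
  prof <- sliding_window_profile(v, window = 25, step = 5)
  expect_equal(nrow(prof), 16)  # floor((100-25)/5) + 1
  # means recompute exactly from the input
  for (k in seq_len(nrow(prof)))
    expect_equal(prof$mean[k],
                 mean(v[prof$start_rank[k]:prof$end_rank[k]]))
  # monotone input -> strictly increasing window means
  expect_true(all(diff(prof$mean) > 0))
  # constant input -> constant means
  expect_true(all(sliding_window_profile(rep(3.5, 60))$mean == 3.5))
  # fewer genes than the window collapses to a single window
  expect_warning(p1 <- sliding_window_profile(1:10, window = 25), "single")
  expect_equal(nrow(p1), 1)
  expect_equal(p1$mean, mean(1:10))
})

test_that("concordance reflects planted mark direction", {
  set.seed(10)
  n <- 200
  res <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    dI = rnorm(n, 0, 1), dEmI = 0)
  res$dE <- res$dI
  active <- data.frame(gene_id = res$gene_id,
                       M_gene = res$dI + rnorm(n, 0, 0.1),
                       n_overlapping_peaks = 1L)
  repressive <- data.frame(gene_id = res$gene_id,
                           M_gene = -res$dI + rnorm(n, 0, 0.1),
                           n_overlapping_peaks = 1L)
  flat <- data.frame(gene_id = res$gene_id, M_gene = 0,
                     n_overlapping_peaks = 1L)
  cr <- concordance_report(res, list(act = active, rep = repressive,
                                     flat = flat), res$gene_id)
  expect_gt(cr$rho[cr$mark == "act"], 0.9)
  expect_lt(cr$rho[cr$mark == "rep"], -0.9)
  expect_true(is.na(cr$rho[cr$mark == "flat"]))  # degenerate
  # too few genes with peaks -> undefined
  few <- active; few$n_overlapping_peaks <- 0L
  few$n_overlapping_peaks[1:5] <- 1L
  cr2 <- concordance_report(res, list(act = few), res$gene_id)
  expect_true(is.na(cr2$rho))
})

test_that("peak tables validate on read", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tM\tA",
               "chr1\t100\t200\t1.5\t4.0"), path)
  pk <- read_diff_peaks(path)
  expect_equal(pk$M, 1.5)
  writeLines(c("chrom\tstart\tend\tM\tA",
               "chr1\t300\t200\t1.5\t4.0"), path)
  expect_error(read_diff_peaks(path), "malformed")
})
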