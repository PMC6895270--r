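test_that("class-wise normalization is scale-invariant", {
  # sample s2 has exactly twice the library of s1, same proportions
  ex <- cbind(c(100, 400, 900), c(200, 800, 1800))
  intr <- cbind(c(50, 60, 70), c(100, 120, 140))
  cnt <- toy_counts(ex, intr)
  norm <- normalize_and_filter(cnt, c("a", "b"), min_expr = 0)
  expect_equal(norm$log_exonic[, 1], norm$log_exonic[, 2])
  expect_equal(norm$log_intronic[, 1], norm$log_intronic[, 2])
  # identical samples normalize identically
  cnt2 <- toy_counts(cbind(ex[, 1], ex[, 1]), cbind(intr[, 1], intr[, 1]))
  norm2 <- normalize_and_filter(cnt2, c("a", "b"), min_expr = 0)
  expect_equal(norm2$log_exonic[, 1], norm2$log_exonic[, 2])
})

test_that("the expression filter requires both classes and catches zeros", {
  ex <- matrix(1000, 2, 4)
  intr <- rbind(rep(1000, 4), rep(0, 4))  # g02 has no intronic signal
  cnt <- toy_counts(ex, intr)
  norm <- normalize_and_filter(cnt, rep(c("a", "b"), 2),
                               min_expr = log2(16), pseudocount = 8)
  expect_equal(norm$retained, "g01")
  # a sample with zero counts in one class is an error
  bad <- toy_counts(matrix(c(10, 10, 0, 0), 2), matrix(5, 2, 2))
  expect_error(normalize_and_filter(bad, c("a", "b")), "zero total")
})

test_that("deltas recover closed-form fold changes at high counts", {
  # 4x exonic change, intronic unchanged -> dE ~ 2, dI ~ 0, dEmI ~ 2
  ex <- cbind(1e5, 1e5, 4e5, 4e5)
  intr <- cbind(1e4, 1e4, 1e4, 1e4)
  cnt <- toy_counts(ex, intr)
  design <- c("a", "a", "b", "b")
  norm <- normalize_and_filter(cnt, design, min_expr = 0)
  d <- compute_deltas(norm, design)
  # library-size normalization within the exonic class absorbs part of a
  # single-gene change, so feed two genes: one changing, one stable ballast
  ex2 <- rbind(c(1e5, 1e5, 4e5, 4e5), c(1e7, 1e7, 1e7, 1e7))
  in2 <- rbind(c(1e4, 1e4, 1e4, 1e4), c(1e6, 1e6, 1e6, 1e6))
  cnt2 <- toy_counts(ex2, in2)
  norm2 <- normalize_and_filter(cnt2, design, min_expr = 0)
  d2 <- compute_deltas(norm2, design)
  g <- d2[d2$gene_id == "g01", ]
  expect_equal(g$dE, 2, tolerance = 0.05)
  expect_equal(g$dI, 0, tolerance = 0.05)
  expect_equal(g$dEmI, g$dE - g$dI)
  # both classes x4 -> purely transcriptional: dEmI ~ 0
  ex3 <- rbind(c(1e5, 1e5, 4e5, 4e5), c(1e7, 1e7, 1e7, 1e7))
  in3 <- rbind(c(1e4, 1e4, 4e4, 4e4), c(1e6, 1e6, 1e6, 1e6))
  cnt3 <- toy_counts(ex3, in3)
  d3 <- compute_deltas(normalize_and_filter(cnt3, design, min_expr = 0),
                       design)
  g3 <- d3[d3$gene_id == "g01", ]
  expect_equal(g3$dI, 2, tolerance = 0.05)
  expect_equal(abs(g3$dEmI) < 0.05, TRUE)
  # identical conditions -> all deltas exactly zero
  d0 <- compute_deltas(normalize_and_filter(
    toy_counts(cbind(ex[, 1], ex[, 1]), cbind(intr[, 1], intr[, 1])),
    c("a", "b"), min_expr = 0), c("a", "b"))
  expect_true(all(d0$dE == 0 & d0$dI == 0 & d0$dEmI == 0))
})

test_that("significance testing flags strong intronic shifts", {
  set.seed(4)
  n <- 200
  mu <- 200
  fc <- rep(1, n); fc[1:10] <- 4  # 10 genes with a 4-fold intronic change
  ex <- sapply(1:6, function(i) rnbinom(n, mu = mu * 10, size = 20))
  intr <- sapply(1:6, function(i)
    rnbinom(n, mu = mu * (if (i > 3) fc else 1), size = 20))
  cnt <- toy_counts(ex, intr)
  design <- rep(c("a", "b"), each = 3)
  sig <- test_significance(cnt, design)
  expect_true(all(sig$fdr_dI[1:10] < 0.05))
  expect_lt(mean(sig$fdr_dI[11:n] < 0.05), 0.05)
  # the same genes shift dEmI too (exonic unchanged, intronic up)
  expect_true(mean(sig$fdr_dEmI[1:10] < 0.05) > 0.8)
})

test_that("fewer than two replicates yields undefined p-values", {
  cnt <- toy_counts(matrix(100, 3, 2), matrix(50, 3, 2))
  expect_warning(sig <- test_significance(cnt, c("a", "b")), "replicates")
  expect_true(all(is.na(sig$p_dI)))
  expect_true(all(is.na(sig$p_dEmI)))
})

test_that("contribution metric applies the threshold and tie rules", {
  res <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    dI = c(0.4, 0.3, 1.5, -2.0),
    dEmI = c(0.8, 0.3, 0.0, 0.0))
  res$dE <- res$dI + res$dEmI
  cm <- contribution_metric(res, threshold = 1)
  # g2 excluded (|x+y| = 0.6); g1 post; g3, g4 transcriptional
  expect_equal(cm$n_considered, 3)
  expect_equal(cm$frac_posttranscriptional, 1 / 3)
  expect_equal(cm$frac_transcriptional, 2 / 3)
  expect_equal(cm$n_ties, 0)
  # signed reading drops the down-regulated g4
  cm2 <- contribution_metric(res, threshold = 1, signed = TRUE)
  expect_equal(cm2$n_considered, 2)
  # exact tie is tallied, not assigned
  tie <- data.frame(gene_id = "t", dI = 1, dEmI = 1)
  cmt <- contribution_metric(tie)
  expect_equal(cmt$n_ties, 1)
  expect_equal(cmt$frac_transcriptional + cmt$frac_posttranscriptional, 0)
  # empty selection
  cm0 <- contribution_metric(res[2, ], threshold = 1)
  expect_equal(cm0$n_considered, 0)
  expect_true(is.na(cm0$frac_transcriptional))
})

test_that("rank_select is deterministic with lexicographic tie-breaks", {
  res <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    dI = seq(0.01, 1, length.out = 100),
                    dEmI = 0, dE = 0)
  expect_equal(rank_select(res, "dI", "up", n = 5),
               sprintf("g%03d", 100:96))
  expect_equal(rank_select(res, "dI", "down", fraction = 0.05),
               sprintf("g%03d", 1:5))
  # all-tied values fall back to gene_id order
  res$dEmI <- 1
  expect_equal(rank_select(res, "dEmI", "up", n = 3),
               c("g001", "g002", "g003"))
  expect_warning(sel <- rank_select(res, "dI", "up", n = 200), "returning")
  expect_length(sel, 100)
  # side-condition selection: low-|dI| universe ranked by dEmI
  res2 <- res
  res2$dEmI <- rev(seq(0.01, 1, length.out = 100))
  sub <- res2[abs(res2$dI) < 0.5, ]
  sel2 <- rank_select(sub, "dEmI", "up", n = 5)
  expect_true(all(abs(res2$dI[match(sel2, res2$gene_id)]) < 0.5))
})

test_that("eisa results round-trip through the TSV writer", {
  cfg <- sim_config(n_genes = 80, seed = 31)
  sim <- simulate_counts(cfg)
  res <- eisa(sim$counts, sim$design, test = FALSE)
  expect_equal(res$dEmI, res$dE - res$dI)
  path <- tempfile(fileext = ".tsv")
  write_eisa_result(res, path, header = "params: none")
  back <- read_eisa_result(path)
  expect_equal(back$dI, res$dI)
  expect_equal(back$gene_id, res$gene_id)
})
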