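test_that("the generator is deterministic given a config", {
  cfg <- sim_config(n_genes = 60, seed = 17, simulate_target_sites = TRUE)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts$exonic, s2$counts$exonic)
  expect_identical(s1$counts$intronic, s2$counts$intronic)
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_predictions(s1$truth, cfg),
                   simulate_predictions(s2$truth, cfg))
  models <- build_gene_models(simulate_annotation(cfg))
  a1 <- simulate_alignments(models, cfg, n_pairs = 300,
                            out_prefix = tempfile("d1"))
  a2 <- simulate_alignments(models, cfg, n_pairs = 300,
                            out_prefix = tempfile("d2"))
  expect_identical(readLines(a1$sam), readLines(a2$sam))
  p1 <- simulate_peaks(models, s1$truth, cfg)
  p2 <- simulate_peaks(models, s1$truth, cfg)
  expect_identical(p1, p2)
})

test_that("realized intron read fraction tracks the configuration", {
  # measured on a null cohort: condition effects intentionally rescale
  # the classes, so the configured fraction is a baseline property
  cfg <- sim_config(n_genes = 500, intron_fraction_of_reads = 0.1,
                    frac_transcriptional = 0, frac_stability = 0,
                    seed = 18)
  sim <- simulate_counts(cfg)
  f <- sum(sim$counts$library_sizes["intronic", ]) /
    sum(sim$counts$library_sizes)
  expect_lt(abs(f - 0.1) / 0.1, 0.10)
})

test_that("planted effects surface in the expected components", {
  # low dispersion and high depth so the NB noise floor
  # (sd ~ sqrt(2 disp / n_rep) / ln 2) sits well under the tolerance
  cfg <- sim_config(n_genes = 600, mean_reads_per_gene = 20000,
                    dispersion = 0.01, seed = 19)
  sim <- simulate_counts(cfg)
  res <- eisa(sim$counts, sim$design, test = FALSE)
  tr <- sim$truth[match(res$gene_id, sim$truth$gene_id), ]
  # estimates are centred on the planted effects
  expect_lt(mean(abs(res$dI - tr$true_transcription_lfc)), 0.15)
  expect_lt(mean(abs(res$dEmI - tr$true_stability_lfc)), 0.2)
  # near-unbiased: with 60% of genes regulated the TMM trimmed-majority
  # assumption is marginal, leaving a residual shift well under 0.1
  expect_lt(abs(mean(res$dI - tr$true_transcription_lfc)), 0.1)
  expect_lt(abs(mean(res$dEmI - tr$true_stability_lfc)), 0.1)
  # transcriptional genes move both classes; stability genes exons only
  tx <- tr$class == "transcriptional"
  st <- tr$class == "stability"
  expect_lt(mean(abs(res$dEmI[tx])), 0.2)
  expect_lt(mean(abs(res$dI[st])), 0.15)
})

test_that("a null configuration gives exchangeable conditions", {
  cfg <- sim_config(n_genes = 400, frac_transcriptional = 0,
                    frac_stability = 0, seed = 20)
  sim <- simulate_counts(cfg)
  res <- eisa(sim$counts, sim$design, test = FALSE)
  expect_lt(abs(mean(res$dI)), 0.05)
  expect_lt(abs(mean(res$dEmI)), 0.05)
})

test_that("deliberately overlapping gene pairs are the ones excluded", {
  cfg <- sim_config(n_genes = 60, overlapping_fraction = 0.1, seed = 21)
  ex <- simulate_annotation(cfg)
  planted <- attr(ex, "expected_excluded")
  expect_length(planted, 2 * floor(0.1 * 60 / 2))
  m <- build_gene_models(ex)
  expect_setequal(m$excluded$gene_id, planted)
})

test_that("site-graded repression lands in the stability component", {
  cfg <- sim_config(n_genes = 400, frac_transcriptional = 0,
                    frac_stability = 0, simulate_target_sites = TRUE,
                    seed = 22)
  truth <- make_truth(cfg)
  expect_true(all(truth$site_type[truth$site_count == 0] == "none"))
  expect_true(all(truth$true_transcription_lfc == 0))
  with_sites <- truth$site_count > 0
  delta <- cfg$delta[truth$site_type[with_sites]]
  expect_equal(truth$true_stability_lfc[with_sites],
               unname(-delta * truth$site_count[with_sites]))
  expect_true(all(truth$true_stability_lfc[!with_sites] == 0))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(frac_transcriptional = 0.8,
                          frac_stability = 0.5), "fractions")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(site_fractions = c(`0` = 0.5, `1` = 0.2,
                                             `2` = 0.2, `3` = 0.2)),
               "sum to 1")
  expect_error(sim_config(delta = c(`6mer` = 0.7, `7mer` = 0.4,
                                    `8mer` = 0.2)), "6mer")
  expect_error(sim_config(intron_fraction_of_reads = 0), "intron_fraction")
})

test_that("GTF round-trip preserves the simulated annotation", {
  cfg <- sim_config(n_genes = 20, seed = 23)
  ex <- simulate_annotation(cfg)
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(ex, gtf)
  back <- read_annotation(gtf)
  expect_equal(length(back), length(ex))
  expect_equal(sort(unique(back$gene_id)), sort(unique(ex$gene_id)))
  m1 <- build_gene_models(ex)
  m2 <- build_gene_models(back)
  expect_identical(m1$genes, m2$genes)
})
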