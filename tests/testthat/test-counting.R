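# Classification rules on the hand-made two-gene model: GA '+', exons
# [101,200] and [301,400], intron [201,300], 10 bp buffer.

test_that("a pair whose first-read 5' end is exonic is EXONIC", {
  m <- toy_models()
  expect_equal(classify_read_pair(toy_obs(150), m), "exonic")
  # 5' end in exon, span reaching into the intron: still exonic
  expect_equal(classify_read_pair(toy_obs(180, 180, 229), m), "exonic")
  # last exonic base
  expect_equal(classify_read_pair(toy_obs(200, 200, 249), m), "exonic")
})

test_that("intronic calls require full containment with >10 bp clearance", {
  m <- toy_models()
  # comfortably inside the intron [201,300]
  expect_equal(classify_read_pair(toy_obs(231, 231, 260), m), "intronic")
  # distance to exon end 200 is 3 bp -> unassigned
  expect_equal(classify_read_pair(toy_obs(203, 203, 227), m), "unassigned")
  # exact boundary: span start 211 is 11 bp from the exon -> intronic
  expect_equal(classify_read_pair(toy_obs(211, 211, 260), m), "intronic")
  # span start 210 is exactly 10 bp away -> fails the strict rule
  expect_equal(classify_read_pair(toy_obs(210, 210, 260), m), "unassigned")
  # clearance violated on the 3' side (exon starts at 301)
  expect_equal(classify_read_pair(toy_obs(261, 261, 295), m), "unassigned")
  # span leaking into the exon
  expect_equal(classify_read_pair(toy_obs(280, 280, 329), m), "unassigned")
})

test_that("strand, uniqueness and location gate the assignment", {
  m <- toy_models()
  # antisense fragment on GA
  expect_equal(classify_read_pair(toy_obs(150, strand = "-"), m),
               "unassigned")
  # but accepted in unstranded mode
  expect_equal(classify_read_pair(toy_obs(150, strand = "-"), m,
                                  strandedness = "unstranded"), "exonic")
  # non-unique mapping
  expect_equal(classify_read_pair(toy_obs(150, unique = FALSE), m),
               "unassigned")
  # intergenic position
  expect_equal(classify_read_pair(toy_obs(5000), m), "unassigned")
  # gene GB is on '-': sense fragment strand is '-'
  expect_equal(classify_read_pair(toy_obs(1050, 1001, 1050,
                                          strand = "-"), m), "exonic")
})

test_that("spliced first reads follow the any-block-5'-start rule", {
  m <- toy_models()
  # 5' block in the intron, second block starting in an exon -> exonic
  obs <- toy_obs(291, 291, 320, block_starts5 = c(291, 301))
  expect_equal(classify_read_pair(obs, m), "exonic")
  # both blocks inside the intron: spliced reads are never intronic
  obs2 <- toy_obs(211, 211, 260, block_starts5 = c(211, 241))
  expect_equal(classify_read_pair(obs2, m), "unassigned")
})

test_that("counting a labelled synthetic BAM reproduces the truth", {
  cfg <- sim_config(n_genes = 60, seed = 21)
  models <- build_gene_models(simulate_annotation(cfg))
  al <- simulate_alignments(models, cfg, n_pairs = 1500,
                            out_prefix = tempfile("cnt"))
  cls <- classify_bam(al$bam, models)
  m <- merge(al$truth, cls, by = "qname")
  expect_equal(nrow(m), 1500)
  expect_identical(mean(m$expected_class == m$class), 1)
  # counted genes agree with the per-gene truth tallies
  cb <- count_bam(al$bam, models)
  tt <- al$truth[al$truth$expected_class != "unassigned", ]
  truth_tab <- table(tt$gene_id, tt$expected_class)
  for (g in rownames(truth_tab)) {
    row <- cb$counts[cb$counts$gene_id == g, ]
    expect_equal(row$exonic, unname(truth_tab[g, "exonic"]))
    expect_equal(row$intronic, unname(truth_tab[g, "intronic"]))
  }
  # library sizes are the column sums; assigned <= unique pairs
  expect_equal(unname(cb$library_sizes["exonic"]), sum(cb$counts$exonic))
  expect_lte(sum(cb$library_sizes),
             cb$diagnostics$n_pairs - cb$diagnostics$n_non_unique)
})

test_that("doubling a BAM exactly doubles every count", {
  cfg <- sim_config(n_genes = 30, seed = 22)
  models <- build_gene_models(simulate_annotation(cfg))
  al <- simulate_alignments(models, cfg, n_pairs = 400,
                            out_prefix = tempfile("dbl"))
  rec <- readLines(al$sam)
  hdr <- grep("^@", rec, value = TRUE)
  body <- grep("^@", rec, value = TRUE, invert = TRUE)
  body2 <- sub("^p", "q", body)  # fresh read names for the copy
  bam2 <- sam_to_bam(c(body, body2), chrom = cfg$chrom, len = 10000000L,
                     prefix = tempfile("dbl2"))
  c1 <- count_bam(al$bam, models)
  c2 <- count_bam(bam2, models)
  expect_equal(c2$counts$exonic, 2L * c1$counts$exonic)
  expect_equal(c2$counts$intronic, 2L * c1$counts$intronic)
})

test_that("empty and malformed inputs are handled explicitly", {
  models <- toy_models()
  bam <- sam_to_bam(character(0))
  cb <- count_bam(bam, models)
  expect_equal(sum(cb$counts$exonic) + sum(cb$counts$intronic), 0)
  expect_equal(unname(cb$library_sizes), c(0L, 0L))
  # missing index
  noidx <- tempfile(fileext = ".bam")
  file.copy(bam, noidx)
  expect_error(count_bam(noidx, models), "index")
  # chromosome mismatch
  bad <- sam_to_bam(sam_pair("r1", 150, chrom = "chrZ"), chrom = "chrZ")
  expect_error(count_bam(bad, models), "chromosome")
})

test_that("count tables round-trip through TSV", {
  cnt <- toy_counts(matrix(1:6, 3), matrix(7:12, 3))
  path <- tempfile(fileext = ".tsv")
  write_counts(cnt, path)
  back <- read_counts(path)
  expect_equal(back$exonic, cnt$exonic)
  expect_equal(back$intronic, cnt$intronic)
  expect_equal(back$library_sizes, cnt$library_sizes)
})
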