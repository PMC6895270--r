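#' Configuration for the synthetic dataset generator
#'
#' Collects every knob of the generator with validated defaults. The
#' defaults describe the reference simulation used throughout the test
#' suite: 2,000 multi-exon genes on one synthetic contig, 3 vs 3 samples,
#' negative-binomial counts with dispersion 0.05, a mean of 2,000 read
#' pairs per gene of which 10% map to introns (so ~200 intronic pairs per
#' gene), and a regulatory mixture of 30% transcriptional-only genes, 30%
#' stability-only genes and 40% unregulated genes with |log2 effect| = 2.
#'
#' Transcriptional effects scale the intronic and exonic means equally;
#' stability effects scale the exonic means only. Per-site miRNA repression
#' (when `simulate_target_sites = TRUE`) subtracts `delta[site_type] *
#' site_count` log2 units from the stability effect, with the default
#' schedule 6mer 0.2, 7mer 0.4, 8mer 0.7.
#'
#' @param n_genes Number of genes.
#' @param n_exons_range Integer range of exons per gene (min 2 unless
#'   `allow_single_exon`).
#' @param exon_length_range,intron_length_range Uniform bp ranges.
#' @param intergenic_gap Gap between consecutive gene spans (bp).
#' @param overlapping_fraction Fraction of genes deliberately placed as
#'   overlapping pairs (to exercise exclusion); default 0.
#' @param chrom Name of the synthetic contig.
#' @param n_per_group Replicates per condition.
#' @param mean_reads_per_gene Mean read pairs per gene per sample
#'   (exonic + intronic), before per-gene expression spread.
#' @param intron_fraction_of_reads Fraction of a gene's reads mapping to
#'   introns.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param frac_transcriptional,frac_stability,frac_coherent Fractions of
#'   transcription-only, stability-only and coherently (both, same sign)
#'   regulated genes; the remainder is unregulated.
#' @param lfc_transcription,lfc_stability Effect magnitudes (log2); signs
#'   are drawn at random per gene.
#' @param expr_sd Log2 SD of the per-gene expression spread.
#' @param simulate_target_sites Assign miRNA site classes and site-graded
#'   repression.
#' @param stability_null_sd SD (log2) of the null-component stability
#'   effect drawn for every gene — the biological spread of mRNA
#'   stability changes unrelated to the planted regulation. Default 0
#'   (exact nulls); Fig-1D-style cohorts use a positive value so that
#'   conditioning on small `|dEmI|` selects genes by true stability
#'   rather than by measurement noise.
#' @param site_fractions Named fractions over site counts `0,1,2,3`
#'   (3 means the 3+ class); must sum to 1.
#' @param delta Named per-site repression (log2) for `6mer`, `7mer`,
#'   `8mer`; must be non-decreasing.
#' @param read_length Read length used by the alignment emitter.
#' @param seed Integer seed; every `simulate_*` call is deterministic
#'   given the config.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_exons_range = c(2L, 6L),
                       exon_length_range = c(120L, 400L),
                       intron_length_range = c(200L, 1200L),
                       intergenic_gap = 1000L,
                       overlapping_fraction = 0,
                       chrom = "chrS",
                       n_per_group = 3L,
                       mean_reads_per_gene = 2000,
                       intron_fraction_of_reads = 0.1,
                       dispersion = 0.05,
                       frac_transcriptional = 0.3,
                       frac_stability = 0.3,
                       frac_coherent = 0,
                       lfc_transcription = 2,
                       lfc_stability = 2,
                       expr_sd = 0.5,
                       simulate_target_sites = FALSE,
                       stability_null_sd = 0,
                       site_fractions = c(`0` = 0.25, `1` = 0.25,
                                          `2` = 0.25, `3` = 0.25),
                       delta = c(`6mer` = 0.2, `7mer` = 0.4, `8mer` = 0.7),
                       read_length = 75L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_exons_range = as.integer(n_exons_range),
              exon_length_range = as.integer(exon_length_range),
              intron_length_range = as.integer(intron_length_range),
              intergenic_gap = as.integer(intergenic_gap),
              overlapping_fraction = overlapping_fraction,
              chrom = chrom, n_per_group = as.integer(n_per_group),
              mean_reads_per_gene = mean_reads_per_gene,
              intron_fraction_of_reads = intron_fraction_of_reads,
              dispersion = dispersion,
              frac_transcriptional = frac_transcriptional,
              frac_stability = frac_stability,
              frac_coherent = frac_coherent,
              lfc_transcription = lfc_transcription,
              lfc_stability = lfc_stability,
              expr_sd = expr_sd,
              simulate_target_sites = isTRUE(simulate_target_sites),
              stability_null_sd = stability_null_sd,
              site_fractions = site_fractions, delta = delta,
              read_length = as.integer(read_length),
              seed = as.integer(seed))
  fr <- cfg$frac_transcriptional + cfg$frac_stability + cfg$frac_coherent
  if (fr > 1 + 1e-9) stop("regulatory fractions sum to ", fr, " > 1")
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (cfg$intron_fraction_of_reads <= 0 || cfg$intron_fraction_of_reads >= 1)
    stop("intron_fraction_of_reads must be in (0, 1)")
  if (is.unsorted(cfg$delta[c("6mer", "7mer", "8mer")]))
    stop("delta must satisfy 6mer <= 7mer <= 8mer")
  if (abs(sum(cfg$site_fractions) - 1) > 1e-9)
    stop("site_fractions must sum to 1")
  if (cfg$stability_null_sd < 0) stop("stability_null_sd must be >= 0")
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (cfg$intron_length_range[1] <= 2L * 10L + cfg$read_length)
    stop("introns must be longer than 2*buffer + read_length for the ",
         "alignment emitter")
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

# sample() on a length-1 vector samples 1:x; these helpers avoid that trap
pick1 <- function(x) x[sample.int(length(x), 1L)]
sample_range <- function(rng, n) {
  seqv <- seq(rng[1], rng[2])
  seqv[sample.int(length(seqv), n, replace = TRUE)]
}

#' Ground-truth regulatory effects for a synthetic cohort
#'
#' Assigns each gene a regulatory class (transcriptional-only,
#' stability-only, coherent, or null) per the configured fractions, draws
#' effect signs at random, and — when target-site simulation is on —
#' assigns miRNA site counts/types and subtracts the site-graded repression
#' from the stability effect (genes without sites keep a null stability
#' component).
#'
#' @param config A [sim_config()].
#' @return data.frame of class `truth_table`: `gene_id`, `class`,
#'   `true_transcription_lfc`, `true_stability_lfc`, `site_count`,
#'   `site_type`.
#' @export
make_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  n_tx <- round(config$frac_transcriptional * n)
  n_st <- round(config$frac_stability * n)
  n_co <- round(config$frac_coherent * n)
  cls <- rep("null", n)
  cls[seq_len(n_tx)] <- "transcriptional"
  cls[n_tx + seq_len(n_st)] <- "stability"
  cls[n_tx + n_st + seq_len(n_co)] <- "coherent"
  cls <- sample(cls)
  sign_tx <- sample(c(-1, 1), n, replace = TRUE)
  sign_st <- sample(c(-1, 1), n, replace = TRUE)
  tx <- ifelse(cls %in% c("transcriptional", "coherent"),
               sign_tx * config$lfc_transcription, 0)
  st <- ifelse(cls == "stability", sign_st * config$lfc_stability,
        ifelse(cls == "coherent", sign_tx * config$lfc_stability, 0))
  if (config$stability_null_sd > 0)
    st <- st + stats::rnorm(n, 0, config$stability_null_sd)
  site_count <- rep(0L, n)
  site_type <- rep("none", n)
  if (config$simulate_target_sites) {
    site_count <- sample(as.integer(names(config$site_fractions)), n,
                         replace = TRUE, prob = config$site_fractions)
    site_type[site_count > 0] <- sample(names(config$delta),
                                        sum(site_count > 0),
                                        replace = TRUE)
    repression <- ifelse(site_count > 0,
                         config$delta[match(site_type,
                                            names(config$delta))] *
                           site_count, 0)
    st <- st - repression
  }
  out <- data.frame(gene_id = sim_gene_ids(n), class = cls,
                    true_transcription_lfc = tx,
                    true_stability_lfc = unname(st),
                    site_count = site_count, site_type = site_type,
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Simulate transcript annotation
#'
#' Lays non-overlapping multi-exon genes end to end along one synthetic
#' contig (one transcript per gene), with an optional fraction of
#' deliberately overlapping gene pairs to exercise the exclusion rule.
#' Strands alternate deterministically.
#'
#' @param config A [sim_config()].
#' @return `GRanges` of exons as produced by [read_annotation()], with an
#'   attribute `expected_excluded`: the gene ids planted as overlapping
#'   pairs.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_genes
  ids <- sim_gene_ids(n)
  n_overlap_pairs <- floor(config$overlapping_fraction * n / 2)
  overlap_genes <- if (n_overlap_pairs > 0)
    ids[seq_len(2L * n_overlap_pairs)] else character()

  # genes start well inside the contig so read spans never underrun base 1
  pos <- 1000L
  rows <- vector("list", n)
  prev_span <- NULL
  for (i in seq_len(n)) {
    k <- pick1(seq(config$n_exons_range[1], config$n_exons_range[2]))
    ex_len <- sample_range(config$exon_length_range, k)
    in_len <- if (k > 1) sample_range(config$intron_length_range, k - 1)
    else integer()
    span_len <- sum(ex_len) + sum(in_len)
    overlap_second <- i %% 2L == 0L && ids[i] %in% overlap_genes
    start <- if (overlap_second) {
      # start inside the previous gene's span so the two spans overlap
      prev_span[1] + (prev_span[2] - prev_span[1]) %/% 2L
    } else pos
    starts <- integer(k); ends <- integer(k)
    p <- start
    for (e in seq_len(k)) {
      starts[e] <- p
      ends[e] <- p + ex_len[e] - 1L
      p <- ends[e] + 1L + if (e < k) in_len[e] else 0L
    }
    strand <- if (i %% 2L == 1L) "+" else "-"
    rows[[i]] <- data.frame(gene_id = ids[i],
                            transcript_id = paste0(ids[i], ".t1"),
                            start = starts, end = ends, strand = strand,
                            stringsAsFactors = FALSE)
    prev_span <- c(start, ends[k])
    pos <- max(pos, ends[k] + 1L + config$intergenic_gap)
  }
  df <- do.call(rbind, rows)
  ex <- GenomicRanges::GRanges(
    seqnames = config$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, gene_id = df$gene_id,
    transcript_id = df$transcript_id)
  attr(ex, "expected_excluded") <- overlap_genes
  ex
}

#' Write exon annotation as GTF
#'
#' @param exons Exon `GRanges` (metadata `gene_id`, `transcript_id`).
#' @param path Output GTF path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(exons, path) {
  gr <- exons
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "eisplit_sim"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Simulate exon/intron read-pair counts
#'
#' Draws negative-binomial counts for two conditions. Intronic means are
#' proportional to the transcription rate; exonic means to transcription
#' rate times mRNA stability, so the expected intronic log2 fold-change
#' equals the true transcription effect and the expected exon-minus-intron
#' change equals the true stability effect.
#'
#' @param config A [sim_config()].
#' @param truth Optional `truth_table`; defaults to [make_truth()] on the
#'   config.
#' @return List with `counts` (an [eisa_counts]), `truth`, and `design`
#'   (factor `ctrl`/`trt`, `n_per_group` each).
#' @export
simulate_counts <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- make_truth(config)
  set.seed(config$seed + 2L)
  n <- nrow(truth)
  rel <- 2^stats::rnorm(n, 0, config$expr_sd)
  rel <- rel / mean(rel)
  mu_in_base <- config$mean_reads_per_gene *
    config$intron_fraction_of_reads * rel
  mu_ex_base <- config$mean_reads_per_gene *
    (1 - config$intron_fraction_of_reads) * rel
  npg <- config$n_per_group
  design <- factor(rep(c("ctrl", "trt"), each = npg),
                   levels = c("ctrl", "trt"))
  sample_ids <- paste0(rep(c("ctrl", "trt"), each = npg),
                       rep(seq_len(npg), 2))
  size <- 1 / config$dispersion
  ex <- matrix(0L, n, 2L * npg, dimnames = list(truth$gene_id, sample_ids))
  intr <- ex
  for (s in seq_len(2L * npg)) {
    trt <- design[s] == "trt"
    mu_i <- if (trt) mu_in_base * 2^truth$true_transcription_lfc else mu_in_base
    mu_e <- if (trt) mu_ex_base * 2^(truth$true_transcription_lfc +
                                     truth$true_stability_lfc) else mu_ex_base
    intr[, s] <- stats::rnbinom(n, mu = mu_i, size = size)
    ex[, s] <- stats::rnbinom(n, mu = mu_e, size = size)
  }
  list(counts = eisa_counts(ex, intr), truth = truth, design = design)
}

#' Emit synthetic alignments with per-pair truth labels
#'
#' Writes a paired-end SAM/BAM whose first reads are planted to exercise
#' every classification rule: exonic (5' end in an exon), spliced exonic
#' (junction read whose 5' block start is exonic), intronic (span wholly
#' inside an intron with more than 10 bp exon clearance), boundary (inside
#' an intron but within 10 bp of an exon), antisense (wrong fragment
#' polarity for the reverse protocol), non-unique (MAPQ below the unique
#' cutoff) and intergenic. Mates overlap the first read on the opposite
#' strand so pairs are properly paired. The emitted truth table gives the
#' class [classify_read_pair()] must return under the reverse protocol.
#'
#' @param models A `gene_models` object built from [simulate_annotation()]
#'   output.
#' @param config A [sim_config()] (read length, chrom, seed).
#' @param n_pairs Total pairs to emit.
#' @param proportions Named numeric over the categories above; normalized
#'   internally.
#' @param out_prefix Path prefix; writes `<prefix>.sam` and a sorted,
#'   indexed `<prefix>.bam`.
#' @return List with `bam`, `sam` and `truth` (data.frame `qname`,
#'   `gene_id`, `category`, `expected_class`).
#' @export
simulate_alignments <- function(models, config, n_pairs = 10000L,
                                proportions = c(exonic = 0.45,
                                                spliced_exonic = 0.05,
                                                intronic = 0.3,
                                                boundary = 0.08,
                                                antisense = 0.07,
                                                nonunique = 0.03,
                                                intergenic = 0.02),
                                out_prefix = tempfile("simbam")) {
  stopifnot(inherits(models, "gene_models"), inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  L <- config$read_length
  g <- models$genes
  ids <- g$gene_id
  # genes with an intron wide enough for a clear intronic placement
  intron_ok <- vapply(ids, function(id) {
    w <- GenomicRanges::width(models$intronic[[id]])
    any(w >= 2L * (models$exon_buffer_bp + 1L) + L)
  }, logical(1))
  multi_exon <- g$n_exons >= 2L
  cats <- sample(names(proportions), n_pairs, replace = TRUE,
                 prob = proportions / sum(proportions))

  recs <- vector("list", n_pairs)
  truth <- vector("list", n_pairs)
  span_end_max <- max(g$end) + 10000L
  for (i in seq_len(n_pairs)) {
    cat_i <- cats[i]
    mapq <- 255L
    cigar <- paste0(L, "M")
    gene <- NA_character_; expected <- "unassigned"
    if (cat_i %in% c("intronic", "boundary")) {
      gene <- pick1(ids[intron_ok])
    } else if (cat_i == "spliced_exonic") {
      gene <- pick1(ids[multi_exon & intron_ok])
    } else if (cat_i != "intergenic") {
      gene <- pick1(ids)
    }
    if (cat_i == "intergenic") {
      # beyond the last gene span
      pos <- span_end_max + sample.int(5000L, 1)
      read_strand <- pick1(c("+", "-"))
    } else {
      gs <- g[g$gene_id == gene, ]
      # sense fragment under the reverse (dUTP) protocol: first read maps
      # antisense to the gene
      read_strand <- if (gs$strand == "+") "-" else "+"
      if (cat_i == "antisense") read_strand <- gs$strand
      if (cat_i == "nonunique") mapq <- pick1(0:10)
      if (cat_i %in% c("exonic", "antisense", "nonunique")) {
        exr <- models$exonic[[gene]]
        # pick an exon and a 5' position inside it; for '-' reads the 5'
        # end is the rightmost aligned base
        e <- pick1(seq_along(exr))
        p5 <- pick1(GenomicRanges::start(exr)[e]:GenomicRanges::end(exr)[e])
        pos <- if (read_strand == "+") p5 else p5 - L + 1L
        expected <- if (cat_i == "exonic") "exonic" else "unassigned"
      } else if (cat_i %in% c("intronic", "boundary")) {
        inr <- models$intronic[[gene]]
        w <- GenomicRanges::width(inr)
        ok <- which(w >= 2L * (models$exon_buffer_bp + 1L) + L)
        r <- pick1(ok)
        is_ <- GenomicRanges::start(inr)[r]; ie_ <- GenomicRanges::end(inr)[r]
        buf <- models$exon_buffer_bp
        if (cat_i == "intronic") {
          # span within [is_+buf, ie_-buf]: clearance > buf everywhere
          pos <- pick1((is_ + buf):(ie_ - buf - L + 1L))
          expected <- "intronic"
        } else {
          # within the intron but within buf bp of the upstream exon
          pos <- is_ + pick1(0:(buf - 1L))
          expected <- "unassigned"
        }
      } else if (cat_i == "spliced_exonic") {
        exr <- models$exonic[[gene]]
        inr <- models$intronic[[gene]]
        # block1 ends at exon1's end, gap over the first intron
        e1 <- 1L
        e1s <- GenomicRanges::start(exr)[e1]; e1e <- GenomicRanges::end(exr)[e1]
        b1 <- min(30L, e1e - e1s + 1L)
        gap <- GenomicRanges::width(inr)[1]
        b2 <- L - b1
        cigar <- paste0(b1, "M", gap, "N", b2, "M")
        pos <- e1e - b1 + 1L
        expected <- "exonic"
      }
    }
    qname <- sprintf("p%06d", i)
    flag1 <- if (read_strand == "+") 99L else 83L
    flag2 <- if (read_strand == "+") 147L else 163L
    seq1 <- strrep("A", L)
    recs[[i]] <- c(
      paste(qname, flag1, config$chrom, pos, mapq, cigar, "=", pos, 0,
            seq1, "*", sep = "\t"),
      paste(qname, flag2, config$chrom, pos, mapq, paste0(L, "M"), "=",
            pos, 0, seq1, "*", sep = "\t"))
    truth[[i]] <- data.frame(qname = qname, gene_id = gene,
                             category = cat_i, expected_class = expected,
                             stringsAsFactors = FALSE)
  }
  sam <- paste0(out_prefix, ".sam")
  header <- c("@HD\tVN:1.6",
              paste0("@SQ\tSN:", config$chrom, "\tLN:",
                     span_end_max + 20000L))
  writeLines(c(header, unlist(recs)), sam)
  bam <- Rsamtools::asBam(sam, destination = out_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  list(bam = bam, sam = sam, truth = do.call(rbind, truth))
}

#' Simulate target predictions from the truth table
#'
#' Builds TargetScan-style prediction tables for one or more predictors.
#' The predicted strength is the planted repression plus predictor noise;
#' ranks (1 = strongest) are unique within a predictor.
#'
#' @param truth A `truth_table` with site annotation
#'   (`simulate_target_sites = TRUE`).
#' @param config A [sim_config()].
#' @param n_predictors Number of predictors; default 2.
#' @param rank_noise_sd SD of the noise on predicted strength; default 0.2.
#' @return data.frame `gene`, `site_count`, `best_site_type`, `rank`,
#'   `predictor` (genes with sites only).
#' @export
simulate_predictions <- function(truth, config, n_predictors = 2L,
                                 rank_noise_sd = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  with_sites <- truth[truth$site_count > 0, , drop = FALSE]
  if (nrow(with_sites) == 0L) stop("truth table has no genes with sites")
  strength <- config$delta[match(with_sites$site_type,
                                 names(config$delta))] *
    with_sites$site_count
  preds <- lapply(seq_len(n_predictors), function(p) {
    noisy <- strength + stats::rnorm(nrow(with_sites), 0, rank_noise_sd)
    data.frame(gene = with_sites$gene_id,
               site_count = with_sites$site_count,
               best_site_type = with_sites$site_type,
               rank = rank(-noisy, ties.method = "first"),
               predictor = paste0("predictor", p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, preds)
}

#' Simulate differential promoter peaks
#'
#' Emits MAnorm-style differential peak tables per histone mark. Active
#' marks get promoter peaks with M equal to the gene's true transcription
#' effect plus noise; repressive marks the negated effect. A configurable
#' fraction of promoters is peak-free and another fraction carries a second
#' decoy peak with a lower A-value (and scrambled M) to exercise the
#' largest-peak rule.
#'
#' @param models A `gene_models` object.
#' @param truth A `truth_table`.
#' @param config A [sim_config()].
#' @param marks Named character: mark name -> `"active"` or `"repressive"`.
#' @param noise_sd SD of the M noise; default 0.3.
#' @param frac_peakless,frac_two_peaks Promoter fractions; defaults 0.1 and
#'   0.2.
#' @param promoter_halfwidth As in [assign_gene_m()]; default 1000.
#' @return Named list (one per mark) of peak data.frames `chrom`, `start`,
#'   `end`, `M`, `A`, `mark`, each carrying an attribute `planted_m`: the
#'   per-gene M of the intended winning peak (0 for peak-free promoters).
#' @export
simulate_peaks <- function(models, truth, config,
                           marks = c(H3K4me3 = "active",
                                     H3K27me3 = "repressive"),
                           noise_sd = 0.3, frac_peakless = 0.1,
                           frac_two_peaks = 0.2,
                           promoter_halfwidth = 1000L) {
  stopifnot(inherits(models, "gene_models"), inherits(config, "sim_config"))
  set.seed(config$seed + 5L)
  ts <- gene_tss(models)
  tx <- truth$true_transcription_lfc[match(ts$gene_id, truth$gene_id)]
  n <- nrow(ts)
  out <- list()
  for (mk in names(marks)) {
    sgn <- if (marks[[mk]] == "active") 1 else -1
    peakless <- stats::runif(n) < frac_peakless
    two <- !peakless & stats::runif(n) < frac_two_peaks
    M_main <- sgn * tx + stats::rnorm(n, 0, noise_sd)
    width <- sample(150:400, n, replace = TRUE)
    off <- sample(-promoter_halfwidth:(promoter_halfwidth %/% 2), n,
                  replace = TRUE)
    start <- pmax(1L, ts$tss + off)
    rows <- data.frame(chrom = ts$chrom, start = start,
                       end = start + width - 1L,
                       M = M_main, A = stats::runif(n, 6, 10), mark = mk,
                       gene = ts$gene_id, main = TRUE,
                       stringsAsFactors = FALSE)
    if (any(two)) {
      w2 <- sample(100:250, sum(two), replace = TRUE)
      s2 <- pmax(1L, ts$tss[two] + sample(0:(promoter_halfwidth %/% 2),
                                          sum(two), replace = TRUE))
      decoy <- data.frame(chrom = ts$chrom[two], start = s2,
                          end = s2 + w2 - 1L,
                          M = -M_main[two] + stats::rnorm(sum(two), 0, 1),
                          A = stats::runif(sum(two), 1, 5), mark = mk,
                          gene = ts$gene_id[two], main = FALSE,
                          stringsAsFactors = FALSE)
      rows <- rbind(rows, decoy)
    }
    rows <- rows[!(rows$gene %in% ts$gene_id[peakless]), , drop = FALSE]
    planted <- stats::setNames(ifelse(peakless, 0, M_main), ts$gene_id)
    pk <- rows[, c("chrom", "start", "end", "M", "A", "mark")]
    row.names(pk) <- NULL
    attr(pk, "planted_m") <- planted
    out[[mk]] <- pk
  }
  out
}

#' Simulate a complete dataset
#'
#' Runs annotation, truth, counts, predictions and peaks with one config
#' (alignment emission is separate — see [simulate_alignments()] — since
#' most analyses work at count level). Optionally writes every table to
#' `out_dir` in the formats the analysis functions read back (GTF, counts
#' TSV, truth TSV, predictions TSV, one peaks TSV per mark).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List `exons`, `models`, `counts`, `truth`, `design`,
#'   `predictions` (NULL unless sites simulated), `peaks`, and `files`
#'   (named paths when `out_dir` given).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  exons <- simulate_annotation(config)
  models <- build_gene_models(exons)
  truth <- make_truth(config)
  # keep the truth of genes excluded from the model out of the count table
  keep <- truth$gene_id %in% models$genes$gene_id
  sim <- simulate_counts(config, truth)
  counts <- eisa_counts(sim$counts$exonic[keep, , drop = FALSE],
                        sim$counts$intronic[keep, , drop = FALSE])
  predictions <- if (config$simulate_target_sites)
    simulate_predictions(truth, config) else NULL
  peaks <- simulate_peaks(models, truth, config)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      gtf = file.path(out_dir, "annotation.gtf"),
      counts = file.path(out_dir, "counts.tsv"),
      truth = file.path(out_dir, "truth.tsv"))
    write_gtf(exons, files$gtf)
    write_counts(counts, files$counts)
    utils::write.table(truth, files$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(predictions)) {
      files$predictions <- file.path(out_dir, "predictions.tsv")
      utils::write.table(predictions, files$predictions, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    for (mk in names(peaks)) {
      f <- file.path(out_dir, paste0("peaks_", mk, ".tsv"))
      utils::write.table(peaks[[mk]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files[[paste0("peaks_", mk)]] <- f
    }
  }
  list(exons = exons, models = models, counts = counts,
       truth = sim$truth, design = sim$design,
       predictions = predictions, peaks = peaks, files = files)
}
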