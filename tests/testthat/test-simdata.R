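test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(background_depth = 0), "background_depth")
  expect_error(sim_config(editing_rate_dist = c(0, 2)), "Beta")
  expect_error(sim_config(peak_width_range = c(300, 100)), "range")
  expect_error(sim_config(spike_set = data.frame(
    spike_id = "s1", modified = TRUE, true_enrichment = 10)), "unmodified")
  expect_error(
    sim_config(condition_design = list(strong = c(WT = 1)),
               category_weights = c(strong = 1)),
    "every condition")
})

test_that("the same seed reproduces reference and experiment exactly", {
  cfg <- tiny_config(42)
  ref1 <- simulate_reference(cfg)
  ref2 <- simulate_reference(cfg)
  expect_identical(as.character(ref1$genome), as.character(ref2$genome))
  expect_identical(ref1$annotation, ref2$annotation)
  exp1 <- simulate_experiment(cfg, ref1$genome, ref1$annotation)
  exp2 <- simulate_experiment(cfg, ref2$genome, ref2$annotation)
  expect_identical(exp1$reads, exp2$reads)
  expect_identical(exp1$spike_counts, exp2$spike_counts)
  expect_identical(exp1$truth, exp2$truth)
})

test_that("a zero-gene configuration yields an empty but valid annotation", {
  cfg <- sim_config(seed = 1, n_genes = 0, n_peaks = 0,
                    contig_length = 5000)
  ref <- simulate_reference(cfg)
  expect_s4_class(ref$annotation, "GRanges")
  expect_length(ref$annotation, 0)
  outdir <- withr::local_tempdir()
  paths <- write_reference(ref, outdir)
  expect_true(file.exists(paths[["annotation"]]))
  gtf_records <- grep("^[^#]", readLines(paths[["annotation"]]), value = TRUE)
  expect_length(gtf_records, 0)
})

test_that("a too-small contig for the requested genes is a configuration error", {
  cfg <- sim_config(seed = 1, n_contigs = 1, contig_length = 3000,
                    n_genes = 10, n_peaks = 0)
  expect_error(simulate_reference(cfg), "too short")
})

test_that("derived intron lengths respect the configured range (exon-gap scan)", {
  cfg <- sim_config(seed = 9, n_contigs = 1, contig_length = 50000,
                    n_genes = 5, n_peaks = 0,
                    gene_structure = list(
                      n_exons_range = c(2L, 4L),
                      exon_length_range = c(150L, 300L),
                      intron_length_range = c(500L, 1000L),
                      utr5_length_range = c(50L, 100L),
                      utr3_length_range = c(50L, 100L)))
  ref <- simulate_reference(cfg)
  outdir <- withr::local_tempdir()
  paths <- write_reference(ref, outdir)
  gtf <- rtracklayer::import(paths[["annotation"]])
  ex <- gtf[gtf$type == "exon"]
  # independent scan: per transcript, gaps between sorted exon intervals
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx]
    s <- sort(GenomicRanges::start(e))
    en <- sort(GenomicRanges::end(e))
    if (length(s) < 2) next
    gaps <- s[-1] - en[-length(en)] - 1L
    expect_true(all(gaps >= 500 & gaps <= 1000),
                info = sprintf("transcript %s gaps: %s", tx,
                               paste(gaps, collapse = ",")))
  }
})

test_that("fold 1 everywhere gives statistically indistinguishable tracks", {
  cfg <- sim_config(seed = 7, n_contigs = 1, contig_length = 40000,
                    n_genes = 5, n_peaks = 4,
                    fold_enrichment_range = c(1, 1),
                    conditions = "WT", n_replicates = 1,
                    condition_design = list(all = c(WT = 1)),
                    category_weights = c(all = 1))
  ref <- simulate_reference(cfg)
  exp <- simulate_experiment(cfg, ref$genome, ref$annotation)
  rd <- exp$reads
  binw <- 500L
  pvals <- c()
  for (lib_pair in list(c("enrichment", "control"))) {
    e <- rd[rd$library == "enrichment", ]
    c_ <- rd[rd$library == "control", ]
    be <- table(factor(e$pos0 %/% binw, levels = 0:(40000 %/% binw - 1)))
    bc <- table(factor(c_$pos0 %/% binw, levels = 0:(40000 %/% binw - 1)))
    for (i in seq_along(be)) {
      tot <- be[i] + bc[i]
      if (tot == 0) next
      pvals <- c(pvals, binom.test(be[i], tot, 0.5)$p.value)
    }
  }
  expect_gt(mean(pvals >= 0.01), 0.97)
})

test_that("planted editing rates match observed alt fractions (binomial CI)", {
  cfg <- tiny_config(13, background_depth = 40)
  ref <- simulate_reference(cfg)
  exp <- simulate_experiment(cfg, ref$genome, ref$annotation)
  rd <- exp$reads[exp$reads$sample_id == "WT_rep1", ]
  sites <- exp$truth$sites
  regions <- exp$truth$peaks[exp$truth$peaks$mod_class == "inosine",
                             c("contig", "start0", "end0")]
  cols <- pileup(rd, ref$genome, regions)
  checked <- 0L; inside_ci <- 0L
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    col <- cols[cols$contig == s$contig & cols$pos0 == s$pos0, ]
    if (nrow(col) != 1 || col$depth < 200) next
    alt <- if (s$strand == "+") col$G_fwd + col$G_rev else col$C_fwd + col$C_rev
    ci <- binom.test(alt, col$depth, conf.level = 0.99)$conf.int
    checked <- checked + 1L
    if (s$rate >= ci[1] && s$rate <= ci[2]) inside_ci <- inside_ci + 1L
  }
  expect_gt(checked, 10)
  expect_gte(inside_ci / checked, 0.9)
})

test_that("a condition scaled to zero carries no planted signal above background", {
  cfg <- tiny_config(17,
                     condition_design = list(strong = c(WT = 1, p150KO = 0,
                                                        dKO = 0)),
                     category_weights = c(strong = 1))
  ref <- simulate_reference(cfg)
  exp <- simulate_experiment(cfg, ref$genome, ref$annotation)
  d0 <- cfg$background_depth
  dko <- exp$reads[exp$reads$sample_id == "dKO_rep1" &
                     exp$reads$library == "enrichment", ]
  ino_peaks <- exp$truth$peaks[exp$truth$peaks$mod_class == "inosine", ]
  for (k in seq_len(nrow(ino_peaks))) {
    p <- ino_peaks[k, ]
    sub <- dko[dko$contig == p$contig & dko$strand == p$strand &
                 dko$mbc_class == "inosine" &
                 dko$pos0 < p$end0 & dko$pos0 + dko$length > p$start0, ]
    mean_depth <- sum(pmin(sub$pos0 + sub$length, p$end0) -
                        pmax(sub$pos0, p$start0)) / (p$end0 - p$start0)
    expect_lt(mean_depth, 1.6 * d0)
  }
})

test_that("read alt-base overrides are conserved with the planted truth", {
  cfg <- tiny_config(19)
  ref <- simulate_reference(cfg)
  exp <- simulate_experiment(cfg, ref$genome, ref$annotation)
  ov <- exp$reads$overrides[exp$reads$overrides != ""]
  toks <- unlist(strsplit(ov, ";", fixed = TRUE))
  pos <- as.integer(sub(":.*", "", toks))
  # every override is a planted site (no error model)
  expect_true(all(pos %in% exp$truth$sites$pos0))
  # in WT, well-covered sites with appreciable rates leave a footprint
  wt <- exp$reads[exp$reads$condition == "WT" & exp$reads$overrides != "", ]
  wt_pos <- as.integer(sub(":.*", "",
                           unlist(strsplit(wt$overrides, ";", fixed = TRUE))))
  # restrict to genes with full wild-type signal (a p150KO-specific gene
  # is by design unedited in WT)
  cats <- exp$truth$gene_categories
  wt_genes <- cats$gene_id[cats$category != "p150KO_specific"]
  sts <- exp$truth$sites
  strong_sites <- sts$pos0[sts$rate > 0.2 & sts$gene_id %in% wt_genes]
  expect_gt(mean(strong_sites %in% wt_pos), 0.95)
})

test_that("control coverage matches the background depth (coverage law)", {
  cfg <- tiny_config(23)
  ref <- simulate_reference(cfg)
  exp <- simulate_experiment(cfg, ref$genome, ref$annotation)
  ctl <- exp$reads[exp$reads$sample_id == "WT_rep1" &
                     exp$reads$library == "control" &
                     exp$reads$mbc_class == "inosine" &
                     exp$reads$strand == "+", ]
  clen <- cfg$contig_length
  rl <- cfg$read_length
  depth <- brute_force_coverage(ctl, clen)
  # interior positions (edge ramps excluded); non-peak regions only
  interior <- (rl + 1):(clen - rl)
  pk <- exp$truth$peaks
  in_peak <- rep(FALSE, clen)
  for (k in seq_len(nrow(pk))) {
    in_peak[(pk$start0[k] + 1):pk$end0[k]] <- TRUE
  }
  sel <- interior[!in_peak[interior]]
  n_reads <- nrow(ctl)
  se <- sqrt(n_reads) * rl / clen
  expect_lt(abs(mean(depth[sel]) - cfg$background_depth), 3 * se + 0.2)
})

test_that("spike counts reflect the configured true enrichment", {
  cfg <- tiny_config(29)
  ref <- simulate_reference(cfg)
  exp <- simulate_experiment(cfg, ref$genome, ref$annotation)
  sc <- exp$spike_counts
  ratio <- sc$count_enriched / sc$count_control
  expected <- cfg$spike_set$true_enrichment[match(sc$spike_id,
                                                  cfg$spike_set$spike_id)]
  expect_true(all(abs(ratio / expected - 1) < 0.25))
})

test_that("experiment tables round-trip through the documented TSV forms", {
  cfg <- sim_config(seed = 31, n_contigs = 1, contig_length = 12000,
                    n_genes = 3, n_peaks = 2, background_depth = 10)
  ref <- simulate_reference(cfg)
  exp <- simulate_experiment(cfg, ref$genome, ref$annotation)
  outdir <- withr::local_tempdir()
  paths <- write_experiment(exp, outdir)
  back <- read_alignment_table(paths[["reads"]])
  expect_identical(back$read_id, exp$reads$read_id)
  expect_identical(back$pos0, exp$reads$pos0)
  expect_identical(back$overrides, exp$reads$overrides)
})
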