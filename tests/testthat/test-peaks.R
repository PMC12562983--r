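test_that("coverage matches single-read and additivity expectations", {
  clens <- c(c1 = 200L)
  one <- make_reads(pos0 = 10L, length = 50L)
  cov <- build_coverage(one, clens)
  tr <- cov[["c1|+|inosine"]]
  expect_equal(tr$depth[11:60], rep(1L, 50))
  expect_equal(sum(tr$depth), 50L)

  two <- make_reads(pos0 = c(10L, 10L), length = 50L,
                    umi = c("AAAA", "CCCC"))
  tr2 <- build_coverage(two, clens)[["c1|+|inosine"]]
  expect_equal(tr2$depth[11:60], rep(2L, 50))
})

test_that("coverage equals a brute-force per-position counting oracle", {
  set.seed(77)
  clens <- c(c1 = 500L)
  rd <- make_reads(pos0 = sample(0:450, 120, TRUE), length = 30L,
                   umi = sprintf("u%03d", 1:120))
  tr <- build_coverage(rd, clens)[["c1|+|inosine"]]
  expect_equal(tr$depth, brute_force_coverage(rd, 500L))
})

test_that("a read beyond the contig end is an error naming the read", {
  clens <- c(c1 = 100L)
  rd <- make_reads(pos0 = 80L, length = 50L, read_id = "runaway")
  expect_error(build_coverage(rd, clens), "runaway")
})

test_that("the spike enrichment factor is the ratio of recovery ratios", {
  expect_equal(spike_enrichment_factor(data.frame(
    modified = c(TRUE, FALSE),
    count_enriched = c(1000, 100),
    count_control = c(100, 100))), 10)
  expect_equal(spike_enrichment_factor(data.frame(
    modified = c(TRUE, FALSE),
    count_enriched = c(500, 500),
    count_control = c(500, 500))), 1)
  expect_error(spike_enrichment_factor(data.frame(
    modified = c(TRUE, FALSE),
    count_enriched = c(100, 100),
    count_control = c(100, 0))), "spike_control_zero")
  expect_error(spike_enrichment_factor(data.frame(
    modified = TRUE, count_enriched = 10, count_control = 10)),
    "unmodified")
})

test_that("spike scaling is linear and composes", {
  pk <- data.frame(fold_enrichment = c(10, 4))
  expect_equal(scale_peaks(pk, 1), pk)
  expect_equal(scale_peaks(pk, 2)$fold_enrichment, c(5, 2))
  twice <- scale_peaks(scale_peaks(pk, 3), 3)
  once <- scale_peaks(pk, 9)
  expect_equal(twice$fold_enrichment, once$fold_enrichment)
  expect_error(scale_peaks(pk, 0), "positive")
})

test_that("identical tracks yield no peaks", {
  depth <- rep(20, 2000)
  out <- call_peaks(make_track(depth), make_track(depth), peak_params())
  expect_equal(nrow(out), 0)
})

test_that("a planted rectangle is recovered as one peak with the right fold", {
  enr <- rep(20, 2000); enr[901:1100] <- 200  # 10x over [900, 1100)
  ctl <- rep(20, 2000)
  p <- peak_params(smooth_window = 5, pseudocount = 1)
  out <- call_peaks(make_track(enr), make_track(ctl), p)
  expect_equal(nrow(out), 1)
  expect_lte(out$start0, 900); expect_gte(out$end0, 1100)
  expect_lt(abs(out$fold_enrichment - 10) / 10, 0.1)
  # boundaries within one smoothing window of the truth
  expect_lte(abs(out$start0 - 900), 5)
  expect_lte(abs(out$end0 - 1100), 5)
  expect_true(out$summit >= out$start0 && out$summit < out$end0)
  expect_equal(out$max_depth, 200)
})

test_that("two separated rectangles give two peaks in coordinate order", {
  enr <- rep(20, 3000)
  enr[501:700] <- 200
  enr[2001:2200] <- 200
  ctl <- rep(20, 3000)
  out <- call_peaks(make_track(enr), make_track(ctl),
                    peak_params(smooth_window = 5))
  expect_equal(nrow(out), 2)
  expect_lt(out$end0[1], out$start0[2])
  expect_lte(abs(out$start0[1] - 500), 5)
  expect_lte(abs(out$start0[2] - 2000), 5)
})

test_that("peaks are disjoint and prominence filtering is monotone", {
  set.seed(501)
  enr <- rpois(20000, 20)
  enr[3001:3200] <- rpois(200, 200)
  enr[3260:3400] <- rpois(141, 150)
  ctl <- rpois(20000, 20)
  counts <- vapply(c(0.5, 1, 2, 4), function(mp) {
    out <- call_peaks(make_track(enr), make_track(ctl),
                      peak_params(min_prominence = mp))
    if (nrow(out) > 1) {
      o <- order(out$start0)
      expect_true(all(out$end0[o][-nrow(out)] <= out$start0[o][-1]))
    }
    nrow(out)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("mismatched track lengths are an error", {
  expect_error(call_peaks(make_track(rep(1, 10)), make_track(rep(1, 20))),
               "length")
  expect_error(
    call_peaks(make_track(rep(1, 10)),
               make_track(rep(1, 10), strand = "-")), "contig/strand")
})

test_that("PHRED transform of the posterior behaves at the anchors", {
  expect_equal(q_from_posterior(0.5), -10 * log10(0.5), tolerance = 1e-12)
  expect_equal(round(q_from_posterior(0.5), 2), 3.01)
  expect_equal(q_from_posterior(1), 100)
  expect_equal(q_from_posterior(1 - 1e-12), 100)
  expect_equal(q_from_posterior(0), 0, tolerance = 1e-9)
})

test_that("the compiled HMM decode agrees with a pure-R forward-backward", {
  set.seed(88)
  x <- c(rnorm(150, 0, 0.3), rnorm(30, 4, 0.8), rnorm(150, 0, 0.3))
  fit <- fit_enrichment_hmm(x)
  expect_false(fit$degenerate)
  g <- r_hmm_posterior(x, fit$mu, fit$sd, fit$A, fit$pi0)
  expect_equal(fit$posterior_enriched, g[, fit$enriched_state],
               tolerance = 1e-8)
  # the fitted enriched state should sit near the planted high level
  expect_gt(max(fit$mu), 3)
  expect_lt(min(fit$mu), 0.5)
  expect_gt(mean(fit$posterior_enriched[151:180]), 0.9)
  expect_lt(mean(fit$posterior_enriched[c(1:150, 181:330)]), 0.1)
})

test_that("a constant signal degenerates to a half-half posterior", {
  fit <- fit_enrichment_hmm(rep(1.5, 50))
  expect_true(fit$degenerate)
  expect_equal(fit$posterior_enriched, rep(0.5, 50))
  expect_equal(q_from_posterior(mean(fit$posterior_enriched)),
               -10 * log10(0.5))
})

test_that("a planted peak outscores every same-width background window", {
  worse <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    enr <- rpois(5000, 20); enr[2001:2200] <- rpois(200, 200)
    ctl <- rpois(5000, 20)
    p <- peak_params()
    te <- make_track(enr); tc <- make_track(ctl)
    pk <- call_peaks(te, tc, p)
    planted <- pk[pk$start0 < 2200 & pk$end0 > 2000, ]
    expect_equal(nrow(planted), 1)
    # score the planted peak and a grid of background intervals together
    bg_starts <- seq(0, 1600, by = 400)
    fake <- data.frame(contig = "c1", start0 = c(planted$start0, bg_starts),
                       end0 = c(planted$end0, bg_starts + 200),
                       strand = "+", mod_class = "inosine",
                       summit = c(planted$summit, bg_starts + 100),
                       fold_enrichment = 1, max_depth = 20, q_score = NA)
    scored <- score_confidence(fake, te, tc, p)
    if (scored$q_score[1] <= max(scored$q_score[-1])) worse <- worse + 1L
  }
  expect_equal(worse, 0L)
})

test_that("peaks must be scored before high-confidence filtering", {
  pk <- data.frame(q_score = NA_real_, max_depth = 10)
  expect_error(filter_high_confidence(pk), "scored")
})

test_that("the depth-5 boundary of the high-confidence filter is exact", {
  pk <- data.frame(q_score = c(50, 50, 5), max_depth = c(4L, 5L, 100L),
                   peak_id = c("a", "b", "c"))
  out <- filter_high_confidence(pk, q_min = 13, depth_min = 5)
  expect_identical(out$peak_id, "b")
  expect_equal(nrow(filter_high_confidence(pk, q_min = 0, depth_min = 0)), 3)
})
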