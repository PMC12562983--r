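toy_genome <- function(seq) {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- "c1"
  g
}

test_that("a clean single read pileups to reference-base counts", {
  genome <- toy_genome("ACGTACGTACGTACGTACGT")
  rd <- make_reads(pos0 = 2L, length = 10L)
  cols <- pileup(rd, genome, data.frame(contig = "c1", start0 = 0L,
                                        end0 = 20L))
  covered <- cols[cols$pos0 %in% 2:11, ]
  expect_equal(covered$depth, rep(1L, 10))
  for (i in seq_len(nrow(covered))) {
    expect_equal(covered[[paste0(covered$ref_base[i], "_fwd")]][i], 1L)
  }
  expect_equal(cols$depth[cols$pos0 %in% c(0, 1, 12:19)], rep(0L, 10))
})

test_that("column depth is capped at the configured maximum", {
  genome <- toy_genome(strrep("A", 60))
  n <- 101L
  rd <- make_reads(pos0 = rep(0L, n), length = 50L,
                   umi = sprintf("u%04d", seq_len(n)),
                   read_id = sprintf("r%04d", seq_len(n)))
  cols <- pileup(rd, genome, data.frame(contig = "c1", start0 = 0L,
                                        end0 = 10L), max_depth = 100L)
  expect_equal(cols$depth, rep(100L, 10))
  expect_equal(cols$A_fwd, rep(100L, 10))
})

test_that("pileup counts match a brute-force per-read tally with overrides", {
  set.seed(909)
  genome <- toy_genome(paste(sample(c("A", "C", "G", "T"), 300,
                                    replace = TRUE), collapse = ""))
  n <- 80
  rd <- make_reads(pos0 = sample(0:250, n, TRUE), length = 50L,
                   strand = sample(c("+", "-"), n, TRUE),
                   umi = sprintf("u%03d", 1:n),
                   read_id = sprintf("r%03d", 1:n))
  # plant overrides on some reads at positions they cover
  refc <- strsplit(as.character(genome[[1]]), "")[[1]]
  for (i in sample(n, 25)) {
    p <- rd$pos0[i] + sample(0:49, 1)
    b <- sample(setdiff(c("A", "C", "G", "T"), refc[p + 1]), 1)
    rd$overrides[i] <- sprintf("%d:%s", p, b)
  }
  cols <- pileup(rd, genome, data.frame(contig = "c1", start0 = 50L,
                                        end0 = 150L))
  # oracle: explicit per-read per-position walk
  bases <- c("A", "C", "G", "T")
  for (p in seq(50, 149, by = 7)) {
    exp_counts <- matrix(0L, 2, 4, dimnames = list(c("+", "-"), bases))
    for (i in seq_len(n)) {
      if (rd$pos0[i] <= p && p < rd$pos0[i] + 50) {
        b <- refc[p + 1]
        if (rd$overrides[i] != "" &&
            as.integer(sub(":.*", "", rd$overrides[i])) == p) {
          b <- sub(".*:", "", rd$overrides[i])
        }
        exp_counts[rd$strand[i], b] <- exp_counts[rd$strand[i], b] + 1L
      }
    }
    col <- cols[cols$pos0 == p, ]
    for (b in bases) {
      expect_equal(col[[paste0(b, "_fwd")]], exp_counts["+", b])
      expect_equal(col[[paste0(b, "_rev")]], exp_counts["-", b])
    }
    expect_equal(col$depth, sum(exp_counts))
  }
})

test_that("a region outside the genome is an error", {
  genome <- toy_genome(strrep("A", 100))
  expect_error(pileup(make_reads(0L), genome,
                      data.frame(contig = "c1", start0 = 50L, end0 = 150L)),
               "outside")
})

make_col <- function(pos0, ref, counts_fwd = c(A = 0, C = 0, G = 0, T = 0),
                     counts_rev = c(A = 0, C = 0, G = 0, T = 0),
                     contig = "c1") {
  data.frame(contig = contig, pos0 = pos0, ref_base = ref,
             A_fwd = counts_fwd[["A"]], C_fwd = counts_fwd[["C"]],
             G_fwd = counts_fwd[["G"]], T_fwd = counts_fwd[["T"]],
             A_rev = counts_rev[["A"]], C_rev = counts_rev[["C"]],
             G_rev = counts_rev[["G"]], T_rev = counts_rev[["T"]],
             depth = sum(counts_fwd) + sum(counts_rev),
             stringsAsFactors = FALSE)
}

ino_peak <- data.frame(peak_id = "pk1", contig = "c1", start0 = 0L,
                       end0 = 1000L, strand = "+", mod_class = "inosine",
                       stringsAsFactors = FALSE)

test_that("the four site-filter clauses are enforced exactly", {
  # rate exactly 0.10 at depth 20 inside the peak: reported
  col <- make_col(100L, "A", c(A = 18, C = 0, G = 2, T = 0))
  out <- call_editing_sites(col, ino_peak)
  expect_equal(nrow(out), 1)
  expect_equal(out$rate, 0.10)
  # depth exactly 5 (strict > 5): rejected
  col5 <- make_col(100L, "A", c(A = 4, C = 0, G = 1, T = 0))
  expect_equal(nrow(call_editing_sites(col5, ino_peak)), 0)
  # depth 6 at 1/6 rate: reported
  col6 <- make_col(100L, "A", c(A = 5, C = 0, G = 1, T = 0))
  expect_equal(nrow(call_editing_sites(col6, ino_peak)), 1)
  # outside every peak: rejected even at rate 0.5, depth 100
  far <- make_col(5000L, "A", c(A = 50, C = 0, G = 50, T = 0))
  expect_equal(nrow(call_editing_sites(far, ino_peak)), 0)
  # rate below 10 percent: rejected
  low <- make_col(100L, "A", c(A = 95, C = 0, G = 5, T = 0))
  expect_equal(nrow(call_editing_sites(low, ino_peak)), 0)
  # m6a peaks never host editing sites
  m6a_peak <- transform(ino_peak, mod_class = "m6a")
  expect_equal(nrow(call_editing_sites(col, m6a_peak)), 0)
})

test_that("minus-strand sites are the reverse-complement image (T to C)", {
  # minus-strand gene context: an A-to-I edit reads as T>C on the
  # reference-forward strand; oracle built from a constructed genome
  genome <- toy_genome(paste0(strrep("C", 50), "T", strrep("C", 49)))
  minus_peak <- transform(ino_peak, strand = "-", end0 = 100L)
  n <- 40L
  rd <- make_reads(pos0 = rep(20L, n), length = 50L, strand = "-",
                   umi = sprintf("u%02d", 1:n),
                   read_id = sprintf("r%02d", 1:n))
  edited <- 1:12  # 30 percent
  rd$overrides[edited] <- "50:C"
  cols <- pileup(rd, genome, data.frame(contig = "c1", start0 = 45L,
                                        end0 = 55L))
  out <- call_editing_sites(cols, minus_peak)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos0, 50L)
  expect_identical(out$strand, "-")
  expect_equal(out$rate, 12 / 40)
  expect_equal(out$alt_count, 12L)
  # an A-context column never fires inside a minus-strand peak
  genomeA <- toy_genome(paste0(strrep("C", 50), "A", strrep("C", 49)))
  rdA <- rd; rdA$overrides[edited] <- "50:G"
  colsA <- pileup(rdA, genomeA, data.frame(contig = "c1", start0 = 45L,
                                           end0 = 55L))
  expect_equal(nrow(call_editing_sites(colsA, minus_peak)), 0)
})

test_that("every reported site re-checks against the filter clauses", {
  set.seed(246)
  genome <- toy_genome(paste(sample(c("A", "C", "G", "T"), 2000,
                                    replace = TRUE), collapse = ""))
  n <- 400
  rd <- make_reads(pos0 = sample(0:1950, n, TRUE), length = 50L,
                   umi = sprintf("u%04d", 1:n),
                   read_id = sprintf("r%04d", 1:n))
  refc <- strsplit(as.character(genome[[1]]), "")[[1]]
  a_pos <- which(refc == "A") - 1L
  for (p in sample(a_pos[a_pos < 1000], 20)) {
    cov <- which(rd$pos0 <= p & p < rd$pos0 + 50)
    hit <- cov[runif(length(cov)) < 0.5]
    if (length(hit)) {
      rd$overrides[hit] <- ifelse(rd$overrides[hit] == "",
                                  sprintf("%d:G", p),
                                  paste0(rd$overrides[hit],
                                         sprintf(";%d:G", p)))
    }
  }
  cols <- pileup(rd, genome, data.frame(contig = "c1", start0 = 0L,
                                        end0 = 1000L))
  out <- call_editing_sites(cols, ino_peak)
  expect_gt(nrow(out), 0)
  for (i in seq_len(nrow(out))) {
    s <- out[i, ]
    expect_true(s$pos0 >= ino_peak$start0 && s$pos0 < ino_peak$end0)
    expect_gt(s$depth, 5)
    expect_gte(s$rate, 0.10)
    expect_identical(refc[s$pos0 + 1], "A")
  }
  # tightening either threshold never increases the site count
  expect_lte(nrow(call_editing_sites(cols, ino_peak, min_rate = 0.2)),
             nrow(out))
  expect_lte(nrow(call_editing_sites(cols, ino_peak,
                                     min_depth_exclusive = 10)),
             nrow(out))
})

test_that("editing density is sites per 100 bases", {
  pk <- data.frame(start0 = 0L, end0 = 100L)
  expect_equal(editing_density(data.frame()[0, , drop = FALSE], pk), 0)
  sites8 <- data.frame(pos0 = 1:8)
  expect_equal(editing_density(sites8, pk), 8)
  pk950 <- data.frame(start0 = 50L, end0 = 1000L)
  expect_equal(editing_density(data.frame(pos0 = 1:19), pk950), 2)
  expect_error(editing_density(sites8, data.frame(start0 = 5L, end0 = 5L)),
               "width")
})

test_that("the VCF writer emits valid v4.2 records", {
  sites <- data.frame(contig = c("c1", "c1"), pos0 = c(99L, 199L),
                      strand = c("+", "-"), depth = c(20L, 30L),
                      ref_count = c(18L, 21L), alt_count = c(2L, 9L),
                      rate = c(0.1, 0.3), peak_id = c("pk1", "pk2"),
                      stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_sites_vcf(sites, f, sample_name = "s1",
                  contig_lengths = c(c1 = 1000L))
  lines <- readLines(f)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  body <- grep("^[^#]", lines, value = TRUE)
  expect_length(body, 2)
  f1 <- strsplit(body[1], "\t")[[1]]
  expect_identical(f1[1:5], c("c1", "100", ".", "A", "G"))
  expect_match(f1[8], "PEAK_ID=pk1;STRAND=\\+;EDIT_RATE=0.1")
  expect_identical(f1[10], "20:18,2")
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_identical(f2[c(2, 4, 5)], c("200", "T", "C"))
})
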