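# Independent oracles and small constructors used across the suite.

# Pure-R scaled forward-backward for a 2-state Gaussian HMM: decodes the
# posterior of each state under fixed parameters. Used to cross-check the
# compiled implementation.
r_hmm_posterior <- function(x, mu, sd, A, pi0) {
  n <- length(x)
  B <- cbind(dnorm(x, mu[1], sd[1]), dnorm(x, mu[2], sd[2]))
  B[B < 1e-300] <- 1e-300
  alpha <- matrix(0, n, 2)
  beta <- matrix(0, n, 2)
  cv <- numeric(n)
  a <- pi0 * B[1, ]
  cv[1] <- sum(a)
  alpha[1, ] <- a / cv[1]
  for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% A) * B[t, ]
    cv[t] <- sum(a)
    alpha[t, ] <- a / cv[t]
  }
  beta[n, ] <- 1
  for (t in (n - 1):1) {
    b <- A %*% (B[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / cv[t + 1]
  }
  g <- alpha * beta
  g / rowSums(g)
}

# O(N * L) per-position read-count oracle.
brute_force_coverage <- function(reads, clen) {
  depth <- integer(clen)
  for (i in seq_len(nrow(reads))) {
    span <- (reads$pos0[i] + 1L):(reads$pos0[i] + reads$length[i])
    depth[span] <- depth[span] + 1L
  }
  depth
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxv <- (sum_a + sum_b) / 2
  if (maxv == expected) return(1)
  (sum_ij - expected) / (maxv - expected)
}

# Coverage-track constructor for hand-built depth vectors.
make_track <- function(depth, contig = "c1", strand = "+",
                       mod_class = "inosine") {
  list(contig = contig, strand = strand, mod_class = mod_class,
       depth = as.numeric(depth))
}

# Mapped-read data.frame constructor with defaults.
make_reads <- function(pos0, length = 50L, contig = "c1", strand = "+",
                       mbc_class = "inosine", umi = NULL, read_id = NULL,
                       overrides = "") {
  n <- length(pos0)
  data.frame(
    read_id = read_id %||% sprintf("r%04d", seq_len(n)),
    contig = contig, pos0 = as.integer(pos0), strand = strand,
    length = as.integer(length), mbc_class = mbc_class,
    umi = umi %||% rep("AAAA", n), overrides = overrides,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small three-condition configuration used by the integration tests.
tiny_config <- function(seed, background_depth = 30, ...) {
  sim_config(seed = seed, n_contigs = 1L, contig_length = 30000L,
             n_genes = 6L, n_peaks = 5L,
             background_depth = background_depth, ...)
}

# Single-condition (wild-type only) configuration for peak-recovery runs.
wt_only_config <- function(seed, ...) {
  sim_config(seed = seed, n_contigs = 1L, contig_length = 20000L,
             n_genes = 5L, n_peaks = 4L, background_depth = 20,
             conditions = "WT", n_replicates = 1L,
             condition_design = list(all = c(WT = 1)),
             category_weights = c(all = 1), ...)
}

# Jaccard overlap of two half-open intervals.
jaccard_interval <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  inter / union
}
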