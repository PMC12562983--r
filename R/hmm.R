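# Two-state (background / enriched) Gaussian hidden Markov model used to
# turn the smoothed enrichment signal into a posterior that a region is
# genuinely enriched. Fitting is fully deterministic: quantile-split
# initialization, fixed iteration cap, fixed tolerance — no RNG involved.
# The Baum-Welch inner loops run in C++ (src/hmm_em.cpp).

HMM_MAX_ITER <- 100L
HMM_TOL <- 1e-6
HMM_SD_FLOOR <- 1e-4
Q_EPS <- 1e-10

#' Fit a two-state Gaussian HMM to a signal vector
#'
#' Baum-Welch EM with deterministic initialization: observations are split
#' at their median into low/high groups which seed the two states' means
#' and standard deviations; transitions start sticky (0.95 stay
#' probability). Iteration stops after 100 rounds or when the
#' log-likelihood improves by less than `1e-6`. The enriched state is the
#' one with the higher fitted mean. A signal with (numerically) no
#' variance cannot support two states; the fit is then flagged degenerate
#' and posteriors default to 0.5.
#'
#' @param x numeric observations (binned smoothed log2 ratio).
#' @return list of class `enrichment_hmm` with `mu`, `sd`, `A` (transition
#'   matrix), `pi0`, `enriched_state` (1 or 2),
#'   `posterior_enriched` (per-observation posterior of the enriched
#'   state), `loglik`, `iterations`, `degenerate`.
#' @export
fit_enrichment_hmm <- function(x) {
  n <- length(x)
  if (n < 4 || stats::sd(x) < 1e-9) {
    fit <- list(mu = c(mean(x), mean(x)), sd = c(HMM_SD_FLOOR, HMM_SD_FLOOR),
                A = matrix(0.5, 2, 2), pi0 = c(0.5, 0.5),
                enriched_state = 2L,
                posterior_enriched = rep(0.5, n), loglik = NA_real_,
                iterations = 0L, degenerate = TRUE)
    class(fit) <- "enrichment_hmm"
    return(fit)
  }
  med <- stats::median(x)
  lo <- x[x <= med]
  hi <- x[x > med]
  if (length(hi) < 2) hi <- sort(x, decreasing = TRUE)[1:2]  # ties at median
  mu <- c(mean(lo), mean(hi))
  sd <- c(stats::sd(lo), stats::sd(hi))
  sd[is.na(sd) | sd < HMM_SD_FLOOR] <- HMM_SD_FLOOR
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  em <- .hmm_em_cpp(x, mu, sd, A, c(0.5, 0.5),
                    HMM_MAX_ITER, HMM_TOL, HMM_SD_FLOOR)
  enriched <- which.max(em$mu)
  fit <- list(mu = em$mu, sd = em$sd, A = em$A, pi0 = em$pi0,
              enriched_state = enriched,
              posterior_enriched = em$gamma[, enriched],
              loglik = em$loglik, iterations = em$iterations,
              degenerate = FALSE)
  class(fit) <- "enrichment_hmm"
  fit
}

# Posterior of the enriched state for a new signal vector under an
# already-fitted model (used to score each coverage track against the
# sample-wide fit).
hmm_posterior <- function(x, fit) {
  if (length(x) == 0) return(numeric())
  if (fit$degenerate) return(rep(0.5, length(x)))
  g <- .hmm_posterior_cpp(x, fit$mu, fit$sd, fit$A, fit$pi0)
  g[, fit$enriched_state]
}

#' PHRED q-score from an enriched-state posterior
#'
#' `q = -10 log10(max(1e-10, 1 - posterior))`, capped at 100.
#'
#' @param posterior posterior probability (or mean posterior) that a
#'   region is enriched.
#' @return PHRED-scaled q-score in `[0, 100]`.
#' @export
#' @examples
#' q_from_posterior(0.5)   # ~3.01
#' q_from_posterior(1)     # 100 (cap)
q_from_posterior <- function(posterior) {
  pmin(-10 * log10(pmax(Q_EPS, 1 - posterior)), 100)
}

# Mean smoothed signal in consecutive windows of w bases.
bin_signal <- function(sm, w) {
  n <- length(sm)
  nbin <- ceiling(n / w)
  bin_of <- rep(seq_len(nbin), each = w)[seq_len(n)]
  as.numeric(tapply(sm, bin_of, mean))
}

#' Assign HMM-posterior confidence scores to peaks
#'
#' Bins the smoothed log2 enrichment signal (bin width = the smoothing
#' window), obtains the per-bin posterior of the enriched HMM state, and
#' scores each peak as the PHRED transform of one minus the mean posterior
#' over the peak's bins. By default the HMM is fitted to this track's
#' binned signal; passing a shared `fit` (from [fit_enrichment_hmm()] on
#' the pooled bins of all of a sample's tracks) anchors the enriched state
#' across tracks, which is how [call_sample_peaks()] scores — a track
#' with no genuine enrichment then yields low posteriors instead of a
#' noise-split two-state fit.
#'
#' @param peaks peak data.frame from [call_peaks()] (same contig/strand).
#' @param enrich,control the coverage tracks the peaks were called on.
#' @param params the [peak_params()] used for calling.
#' @param size_factor the library-size factor used for calling.
#' @param fit optional pre-fitted `enrichment_hmm`.
#' @return `peaks` with `q_score` filled in.
#' @export
score_confidence <- function(peaks, enrich, control, params = peak_params(),
                             size_factor = 1, fit = NULL) {
  if (nrow(peaks) == 0) return(peaks)
  n <- length(enrich$depth)
  if (any(peaks$start0 < 0 | peaks$end0 > n)) {
    stop("peak lies outside the coverage track")
  }
  sm <- enrichment_signal(enrich, control, params, size_factor)
  w <- params$smooth_window
  binned <- bin_signal(sm, w)
  if (is.null(fit)) fit <- fit_enrichment_hmm(binned)
  post <- hmm_posterior(binned, fit)
  peaks$q_score <- vapply(seq_len(nrow(peaks)), function(j) {
    b0 <- (peaks$start0[j] %/% w) + 1L
    b1 <- ((peaks$end0[j] - 1L) %/% w) + 1L
    bins <- b0:b1
    # weight each bin by its base overlap with the peak, so an edge bin
    # that barely touches the peak cannot dilute the posterior
    ov <- pmin(bins * w, peaks$end0[j]) - pmax((bins - 1L) * w,
                                               peaks$start0[j])
    q_from_posterior(sum(post[bins] * ov) / sum(ov))
  }, numeric(1))
  peaks
}
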