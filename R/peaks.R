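#' Peak-calling parameters
#'
#' @param smooth_window centered moving-average width, bases.
#' @param pseudocount pseudocount added to both tracks before the log
#'   ratio, reads.
#' @param min_prominence minimum prominence of a summit on the smoothed
#'   log2 ratio (1 = 2-fold above its saddle).
#' @param min_width minimum peak width, bases.
#' @param q_min minimum PHRED q-score for high confidence (13 corresponds
#'   to posterior ~0.95 that the peak is in the enriched state).
#' @param depth_min minimum enrichment-library depth at the peak maximum.
#' @return list of class `peak_params`.
#' @export
peak_params <- function(smooth_window = 25L, pseudocount = 1,
                        min_prominence = 1, min_width = 30L,
                        q_min = 13, depth_min = 5L) {
  stopifnot(smooth_window >= 1, pseudocount > 0, min_prominence > 0,
            min_width >= 1)
  structure(list(smooth_window = as.integer(smooth_window),
                 pseudocount = pseudocount,
                 min_prominence = min_prominence,
                 min_width = as.integer(min_width),
                 q_min = q_min, depth_min = as.integer(depth_min)),
            class = "peak_params")
}

# Centered moving average with truncated windows at the array edges, so
# the smoothed signal is defined at every position.
smooth_ma <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half <- (w - 1) %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - 1L - half), n)
  cm <- cumsum(c(0, x))
  (cm[hi + 1L] - cm[lo]) / (hi - lo + 1L)
}

# Smoothed log2 enrichment-over-control signal shared by the caller and
# the confidence scorer.
enrichment_signal <- function(enrich, control, params, size_factor) {
  if (length(enrich$depth) != length(control$depth)) {
    stop("enrichment and control tracks have different lengths")
  }
  c0 <- params$pseudocount
  sig <- log2((enrich$depth + c0) / (size_factor * control$depth + c0))
  smooth_ma(sig, params$smooth_window)
}

# Local maxima of x, plateaus collapsed to their middle position.
# Endpoints are not maxima. Returns integer positions.
local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(integer())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- 2:(k - 1L)
  is_max <- r$values[i] > r$values[i - 1L] & r$values[i] > r$values[i + 1L]
  idx <- i[is_max]
  as.integer((starts[idx] + ends[idx]) %/% 2L)
}

# Topographic prominence of each candidate summit: height above the higher
# of the two saddles separating it from the nearest higher terrain (or the
# array end). Scanning runs in C++ (src/prominence.cpp).
summit_prominence <- function(x, pos, min_prom) {
  .summit_prominence_cpp(as.numeric(x), as.integer(pos), min_prom)
}

#' Call candidate peaks from an enrichment and a control coverage track
#'
#' The signal is the log2 ratio of pseudocounted enrichment depth over
#' library-size-scaled control depth, smoothed by a centered moving
#' average. Summits are local maxima with prominence at least
#' `min_prominence`; each peak extends from its summit to where the
#' smoothed signal falls below (summit - prominence/2) or below zero.
#' Overlapping candidate intervals are merged (the merged summit is the
#' highest point). Raw fold enrichment is `2^(max smoothed signal)` in the
#' peak; it is later divided by the spike-in factor by [scale_peaks()].
#'
#' @param enrich,control coverage tracks from [build_coverage()] for the
#'   same contig/strand/class.
#' @param params a [peak_params()].
#' @param size_factor library-size factor: total mapped enrichment reads
#'   over total mapped control reads.
#' @return data.frame of unscored peaks: `contig`, `start0`, `end0`
#'   (0-based half-open), `strand`, `mod_class`, `summit`, `fold_enrichment`
#'   (raw, unscaled), `max_depth`, `q_score` (NA until scored).
#' @export
call_peaks <- function(enrich, control, params = peak_params(),
                       size_factor = 1) {
  if (enrich$contig != control$contig || enrich$strand != control$strand) {
    stop("enrichment and control tracks must cover the same contig/strand")
  }
  sm <- enrichment_signal(enrich, control, params, size_factor)
  empty <- data.frame(
    contig = character(), start0 = integer(), end0 = integer(),
    strand = character(), mod_class = character(), summit = integer(),
    fold_enrichment = numeric(), max_depth = integer(), q_score = numeric(),
    stringsAsFactors = FALSE
  )
  cand <- local_maxima(sm)
  if (length(cand) == 0) return(empty)
  prom <- summit_prominence(sm, cand, params$min_prominence)
  keep <- prom >= params$min_prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0) return(empty)

  n <- length(sm)
  ivs <- t(vapply(seq_along(cand), function(j) {
    p <- cand[j]
    thr <- max(sm[p] - prom[j] / 2, 0)
    s <- p
    while (s > 1L && sm[s - 1L] >= thr) s <- s - 1L
    e <- p
    while (e < n && sm[e + 1L] >= thr) e <- e + 1L
    c(s - 1L, e)  # 0-based half-open
  }, integer(2)))

  # merge overlapping candidate intervals
  o <- order(ivs[, 1], ivs[, 2])
  ivs <- ivs[o, , drop = FALSE]
  ms <- ivs[1, 1]; me <- ivs[1, 2]
  merged <- NULL
  for (j in seq_len(nrow(ivs))[-1]) {
    if (ivs[j, 1] < me) {
      me <- max(me, ivs[j, 2])
    } else {
      merged <- rbind(merged, c(ms, me))
      ms <- ivs[j, 1]; me <- ivs[j, 2]
    }
  }
  merged <- rbind(merged, c(ms, me))

  # fold enrichment: smoothed enrichment depth at its maximum over the
  # library-scaled mean control depth across the peak (both
  # pseudocounted). Estimating the control from the whole peak rather
  # than the summit column keeps the ratio stable against
  # fragment-scale control troughs.
  e_sm <- smooth_ma(enrich$depth, params$smooth_window)
  c0 <- params$pseudocount
  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(j) {
    s0 <- merged[j, 1]; e0 <- merged[j, 2]
    span <- (s0 + 1L):e0
    summit <- span[which.max(sm[span])] - 1L
    fold <- (max(e_sm[span]) + c0) /
      (size_factor * mean(control$depth[span]) + c0)
    data.frame(
      contig = enrich$contig, start0 = s0, end0 = e0,
      strand = enrich$strand, mod_class = enrich$mod_class,
      summit = as.integer(summit),
      fold_enrichment = fold,
      max_depth = as.integer(max(enrich$depth[span])),
      q_score = NA_real_, stringsAsFactors = FALSE
    )
  }))
  out <- out[out$end0 - out$start0 >= params$min_width, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter peaks to the high-confidence set
#'
#' A peak is high-confidence when its PHRED q-score reaches `q_min` and
#' the enrichment library covers its maximum with at least `depth_min`
#' reads.
#'
#' @param peaks scored peak data.frame.
#' @param q_min minimum q-score.
#' @param depth_min minimum enrichment depth at the peak maximum
#'   (default 5).
#' @return the retained rows.
#' @export
filter_high_confidence <- function(peaks, q_min = 13, depth_min = 5L) {
  if (nrow(peaks) == 0) return(peaks)
  if (any(is.na(peaks$q_score))) stop("peaks must be scored before filtering")
  out <- peaks[peaks$q_score >= q_min & peaks$max_depth >= depth_min, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}
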