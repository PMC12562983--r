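#' Spike-in enrichment factor
#'
#' Ratio-of-ratios recovery of modified versus unmodified spike-in
#' controls, used to place peak fold-enrichment on an absolute scale:
#' `(sum enriched_mod / sum control_mod) / (sum enriched_unmod / sum
#' control_unmod)`.
#'
#' @param spikes data.frame with columns `modified` (logical),
#'   `count_enriched`, `count_control`.
#' @return positive scalar enrichment factor.
#' @export
#' @examples
#' spike_enrichment_factor(data.frame(
#'   modified = c(TRUE, FALSE),
#'   count_enriched = c(1000, 100),
#'   count_control = c(100, 100)))  # 10
spike_enrichment_factor <- function(spikes) {
  stopifnot(all(c("modified", "count_enriched", "count_control") %in%
                  names(spikes)))
  if (any(spikes$count_enriched < 0) || any(spikes$count_control < 0)) {
    stop("spike counts must be non-negative")
  }
  mod <- spikes[spikes$modified, , drop = FALSE]
  unmod <- spikes[!spikes$modified, , drop = FALSE]
  if (nrow(mod) == 0 || nrow(unmod) == 0) {
    stop("need at least one modified and one unmodified spike")
  }
  cm <- sum(mod$count_control)
  cu <- sum(unmod$count_control)
  if (cm == 0 || cu == 0) stop("spike_control_zero")
  eu <- sum(unmod$count_enriched)
  if (eu == 0) stop("spike_control_zero")
  (sum(mod$count_enriched) / cm) / (eu / cu)
}

#' Scale peak fold enrichments by the spike-in factor
#'
#' @param peaks peak data.frame with a `fold_enrichment` column.
#' @param factor positive spike-in enrichment factor.
#' @return `peaks` with `fold_enrichment` divided by `factor`; row order
#'   unchanged.
#' @export
scale_peaks <- function(peaks, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("spike factor must be a positive scalar")
  }
  peaks$fold_enrichment <- peaks$fold_enrichment / factor
  peaks
}
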