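#' Aggregate annotated peak scores to gene level
#'
#' The score of a gene in a sample is the maximum spike-scaled fold
#' enrichment over that gene's peaks in that sample (robust to peak
#' fragmentation); a gene absent from a sample scores 0. Condition scores
#' are arithmetic means over the condition's replicates.
#'
#' @param peak_table long data.frame with one row per (annotated peak,
#'   gene): columns `gene_id`, `sample_id`, `condition`,
#'   `fold_enrichment`.
#' @param samples sample sheet data.frame with `sample_id`, `condition`
#'   (defines the full column set, including samples with no peaks).
#' @return list of class `gene_score_matrix`: `scores` (genes x samples),
#'   `condition_scores` (genes x conditions), `condition_map`.
#' @export
gene_scores <- function(peak_table, samples) {
  stopifnot(all(c("gene_id", "sample_id", "fold_enrichment") %in%
                  names(peak_table)),
            all(c("sample_id", "condition") %in% names(samples)))
  pt <- peak_table[peak_table$gene_id != "", , drop = FALSE]
  genes <- sort(unique(pt$gene_id), method = "radix")
  m <- matrix(0, nrow = length(genes), ncol = nrow(samples),
              dimnames = list(genes, samples$sample_id))
  if (nrow(pt) > 0) {
    agg <- stats::aggregate(fold_enrichment ~ gene_id + sample_id, data = pt,
                            FUN = max)
    agg <- agg[agg$sample_id %in% samples$sample_id, , drop = FALSE]
    m[cbind(agg$gene_id, agg$sample_id)] <- agg$fold_enrichment
  }
  conds <- unique(samples$condition)
  cm <- vapply(conds, function(cd) {
    cols <- samples$sample_id[samples$condition == cd]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(length(genes)))
  if (length(genes) == 1) cm <- matrix(cm, nrow = 1, dimnames = list(genes, conds))
  structure(list(scores = m, condition_scores = cm,
                 condition_map = samples[, c("sample_id", "condition")]),
            class = "gene_score_matrix")
}

#' Classify ADAR1 isoform dependency from condition scores
#'
#' Applies the ratio scheme `ratio = WT / (p150KO + 1)` with rules
#' evaluated in order: (1) WT = 0, p150KO = 0, dKO > 1 -> `dko_specific`;
#' (2) WT = 0, p150KO > 1 -> `p150KO_specific`; (3) ratio >= 4 ->
#' `strong`; (4) 1 < ratio < 4 -> `mild`; (5) ratio < 1 ->
#' `independent`; otherwise `unclassified` (the stated partition excludes
#' ratio exactly 1).
#'
#' @param wt,p150ko,dko non-negative score vectors (recycled to a common
#'   length).
#' @return data.frame `wt_score`, `p150ko_score`, `dko_score`, `ratio`,
#'   `category`.
#' @export
#' @examples
#' classify_dependency(8, 1)$category   # "strong" (ratio exactly 4)
#' classify_dependency(0, 2)$category   # "p150KO_specific"
classify_dependency <- function(wt, p150ko, dko = 0) {
  n <- max(length(wt), length(p150ko), length(dko))
  wt <- rep_len(wt, n); p150ko <- rep_len(p150ko, n); dko <- rep_len(dko, n)
  if (any(wt < 0 | p150ko < 0 | dko < 0)) stop("scores must be non-negative")
  ratio <- wt / (p150ko + 1)
  category <- rep("unclassified", n)
  category[ratio < 1] <- "independent"
  category[ratio > 1 & ratio < 4] <- "mild"
  category[ratio >= 4] <- "strong"
  category[wt == 0 & p150ko > 1] <- "p150KO_specific"
  category[wt == 0 & p150ko == 0 & dko > 1] <- "dko_specific"
  data.frame(wt_score = wt, p150ko_score = p150ko, dko_score = dko,
             ratio = ratio, category = category, stringsAsFactors = FALSE)
}

#' Genes common to every replicate
#'
#' @param gene_sets list (length >= 2) of character vectors of gene ids.
#' @return sorted character vector present in every set.
#' @export
common_genes <- function(gene_sets) {
  if (!is.list(gene_sets) || length(gene_sets) < 2) {
    stop("need at least two replicate gene sets")
  }
  sort(Reduce(intersect, gene_sets), method = "radix")
}

#' Percent reduction in peak counts relative to the reference condition
#'
#' When a knockout condition has the same number of replicates as the
#' reference, counts are rank-paired (both sorted decreasingly, pairing
#' clone-wise) and the per-pair reductions `1 - KO/WT` are averaged —
#' the convention that reproduces per-clone reporting and is invariant to
#' the order replicates are listed in. With unequal replicate numbers the
#' ratio of mean counts is used instead. Results are percentages rounded
#' to one decimal.
#'
#' @param peak_counts named list: condition -> numeric vector of
#'   per-replicate peak counts. The reference is `reference` (default
#'   `"WT"`, else the first element).
#' @param reference reference condition name.
#' @return named numeric vector of percent reductions for every
#'   non-reference condition.
#' @export
#' @examples
#' reduction_summary(list(WT = c(2308, 2251), p150KO = c(736, 479),
#'                        dKO = c(4, 2)))
reduction_summary <- function(peak_counts, reference = "WT") {
  stopifnot(is.list(peak_counts), length(peak_counts) >= 2)
  if (!reference %in% names(peak_counts)) reference <- names(peak_counts)[1]
  wt <- peak_counts[[reference]]
  if (any(unlist(peak_counts) < 0)) stop("peak counts must be non-negative")
  if (mean(wt) == 0) stop("reference condition has zero mean peak count")
  ko_names <- setdiff(names(peak_counts), reference)
  out <- vapply(ko_names, function(k) {
    ko <- peak_counts[[k]]
    if (length(ko) == length(wt)) {
      red <- mean(1 - sort(ko, decreasing = TRUE) /
                    sort(wt, decreasing = TRUE))
    } else {
      red <- 1 - mean(ko) / mean(wt)
    }
    round(100 * red, 1)
  }, numeric(1))
  out
}

#' Cluster per-gene score profiles
#'
#' Genes are z-scored across samples (zero-variance genes get z = 0),
#' aggregated to condition means, and clustered by agglomerative
#' hierarchical clustering with Euclidean distance and Ward linkage, cut
#' to `n_clusters`.
#'
#' @param gsm a [gene_scores()] result (or a plain genes x samples
#'   matrix, in which case `condition_map` must be given).
#' @param n_clusters number of clusters (must not exceed the gene count).
#' @param condition_map data.frame `sample_id`, `condition` when `gsm` is
#'   a plain matrix.
#' @return named integer vector: gene -> cluster label.
#' @export
cluster_gene_scores <- function(gsm, n_clusters, condition_map = NULL) {
  if (inherits(gsm, "gene_score_matrix")) {
    m <- gsm$scores
    condition_map <- gsm$condition_map
  } else {
    m <- gsm
    if (is.null(condition_map)) {
      condition_map <- data.frame(sample_id = colnames(m),
                                  condition = colnames(m))
    }
  }
  if (nrow(m) < 2) stop("need at least two genes to cluster")
  if (n_clusters > nrow(m)) stop("n_clusters exceeds the number of genes")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  sdv[is.na(sdv)] <- 0  # a single sample carries no variance
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  conds <- unique(condition_map$condition)
  zc <- vapply(conds, function(cd) {
    cols <- condition_map$sample_id[condition_map$condition == cd]
    rowMeans(z[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  hc <- stats::hclust(stats::dist(zc, method = "euclidean"),
                      method = "ward.D2")
  stats::cutree(hc, k = n_clusters)
}
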