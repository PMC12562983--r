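#' Prepare a sample's coverage tracks and per-class normalization
#'
#' Deduplicates the enrichment and control libraries, builds per-(contig,
#' strand, class) coverage, and computes a per-class library-size factor
#' as the ratio of genome-wide median depths within that class's tracks —
#' robust, unlike total-read ratios, to the enriched minority of the
#' genome, and strictly class-local (each modification class is its own
#' split library). Falls back to the class read-count ratio when the
#' control median is zero.
#'
#' @param reads the sample's mapped reads (`library` column distinguishes
#'   `"enrichment"` from `"control"`).
#' @param contig_lengths named contig length vector.
#' @param params a [peak_params()].
#' @return list: `enr`, `ctl` (deduplicated reads), `cov_e`, `cov_c`
#'   (coverage track lists), `size_factors` (named per class), `bins`
#'   (per enrichment track key, the binned smoothed log2 ratio).
#' @export
prepare_sample_tracks <- function(reads, contig_lengths,
                                  params = peak_params()) {
  enr <- deduplicate(reads[reads$library == "enrichment", , drop = FALSE])
  ctl <- deduplicate(reads[reads$library == "control", , drop = FALSE])
  cov_e <- build_coverage(enr, contig_lengths)
  cov_c <- build_coverage(ctl, contig_lengths)
  ctl_of <- function(tr_e) {
    cov_c[[track_key(tr_e$contig, tr_e$strand, tr_e$mod_class)]] %||%
      empty_track(tr_e$contig, tr_e$strand, tr_e$mod_class,
                  length(tr_e$depth))
  }
  classes <- sort(unique(vapply(cov_e, `[[`, character(1), "mod_class")),
                  method = "radix")
  size_factors <- stats::setNames(vapply(classes, function(cls) {
    e_cls <- cov_e[vapply(cov_e, function(t) t$mod_class == cls, logical(1))]
    med_e <- stats::median(unlist(lapply(e_cls, `[[`, "depth"),
                                  use.names = FALSE))
    med_c <- stats::median(unlist(lapply(e_cls, function(t)
      ctl_of(t)$depth), use.names = FALSE))
    if (isTRUE(med_c > 0)) {
      med_e / med_c
    } else {
      n_c <- sum(ctl$mbc_class == cls)
      if (n_c > 0) sum(enr$mbc_class == cls) / n_c else 1
    }
  }, numeric(1)), classes)
  bins <- lapply(cov_e, function(tr_e) {
    bin_signal(enrichment_signal(tr_e, ctl_of(tr_e), params,
                                 size_factors[[tr_e$mod_class]]),
               params$smooth_window)
  })
  list(enr = enr, ctl = ctl, cov_e = cov_e, cov_c = cov_c,
       ctl_of = ctl_of, size_factors = size_factors, bins = bins)
}

#' Call, score and annotate peaks for one sample
#'
#' Runs the per-sample stages: deduplicate mapped reads per library,
#' build per-(class, strand) coverage, call and HMM-score peaks per track
#' against the solution control, scale fold enrichment by the sample's
#' spike-in factor, and keep the high-confidence set. Every step is
#' strictly per modification class (classes are split libraries), so one
#' class's reads never influence another class's peaks.
#'
#' @param reads the sample's mapped reads (`library` column distinguishes
#'   `"enrichment"` from `"control"`).
#' @param contig_lengths named contig length vector.
#' @param spikes the sample's spike-count table.
#' @param params a [peak_params()].
#' @param sample_id label used for peak ids.
#' @param hmm_fits optional named list (class -> [fit_enrichment_hmm()]
#'   result); [run_pipeline()] supplies fits pooled per class across all
#'   samples so that knockout samples are scored against the enriched
#'   state anchored by wild-type signal. When NULL, each class is fitted
#'   on this sample's own pooled bins.
#' @param prep optional precomputed [prepare_sample_tracks()] result.
#' @return list: `peaks` (high-confidence, with `peak_id`), `all_peaks`
#'   (scored, pre-filter), `dedup_reads` (deduplicated enrichment reads,
#'   for pileup), `spike_factor`, `size_factors`.
#' @export
call_sample_peaks <- function(reads, contig_lengths, spikes,
                              params = peak_params(),
                              sample_id = "sample", hmm_fits = NULL,
                              prep = NULL) {
  if (is.null(prep)) prep <- prepare_sample_tracks(reads, contig_lengths,
                                                   params)
  cov_e <- prep$cov_e
  if (is.null(hmm_fits)) {
    classes <- names(prep$size_factors)
    hmm_fits <- lapply(stats::setNames(classes, classes), function(cls) {
      keep <- vapply(cov_e, function(t) t$mod_class == cls, logical(1))
      fit_enrichment_hmm(unlist(prep$bins[keep], use.names = FALSE))
    })
  }
  peak_list <- list()
  for (key in names(cov_e)) {
    tr_e <- cov_e[[key]]
    tr_c <- prep$ctl_of(tr_e)
    sf <- prep$size_factors[[tr_e$mod_class]]
    pk <- call_peaks(tr_e, tr_c, params, sf)
    if (nrow(pk) == 0) next
    peak_list[[key]] <- score_confidence(pk, tr_e, tr_c, params, sf,
                                         fit = hmm_fits[[tr_e$mod_class]])
  }
  all_peaks <- if (length(peak_list) > 0) {
    do.call(rbind, c(peak_list, list(make.row.names = FALSE)))
  } else {
    data.frame(contig = character(), start0 = integer(), end0 = integer(),
               strand = character(), mod_class = character(),
               summit = integer(), fold_enrichment = numeric(),
               max_depth = integer(), q_score = numeric(),
               stringsAsFactors = FALSE)
  }
  spike_factor <- spike_enrichment_factor(spikes)
  all_peaks <- scale_peaks(all_peaks, spike_factor)
  all_peaks <- all_peaks[order(all_peaks$contig, all_peaks$start0,
                               all_peaks$strand, all_peaks$mod_class,
                               method = "radix"), , drop = FALSE]
  rownames(all_peaks) <- NULL
  if (nrow(all_peaks) > 0) {
    # ids numbered within each class so one class's peaks are unaffected
    # by another class's presence
    idx <- stats::ave(seq_len(nrow(all_peaks)), all_peaks$mod_class,
                      FUN = seq_along)
    all_peaks$peak_id <- sprintf("%s_%s_pk%04d", sample_id,
                                 all_peaks$mod_class, idx)
  } else {
    all_peaks$peak_id <- character(0)
  }
  hi <- filter_high_confidence(all_peaks, params$q_min, params$depth_min)
  list(peaks = hi, all_peaks = all_peaks, dedup_reads = prep$enr,
       spike_factor = spike_factor, size_factors = prep$size_factors)
}

#' Run the full pipeline on a simulated experiment
#'
#' Per sample: peak calling, scoring, spike scaling, high-confidence
#' filtering, editing-site calling inside inosine peaks, and feature
#' annotation. Across samples: gene score aggregation, dependency
#' classification (when the condition design includes WT and p150KO),
#' replicate-common gene sets, peak-count reduction summaries, and Ward
#' clustering of z-scored gene profiles.
#'
#' @param exp a [simulate_experiment()] result.
#' @param ref the matching [simulate_reference()] result.
#' @param params a [peak_params()].
#' @param n_clusters clusters for the gene-profile clustering (skipped if
#'   fewer genes than clusters).
#' @return list with per-sample results (`peaks`, `sites`, `annotations`),
#'   `gene_scores`, `dependency`, `reductions`, `common_wt_genes`,
#'   `clusters`, `region_counts`, `feature_index`, `samples`.
#' @export
run_pipeline <- function(exp, ref, params = peak_params(), n_clusters = 4L) {
  contig_lengths <- stats::setNames(Biostrings::width(ref$genome),
                                    names(ref$genome))
  index <- build_feature_index(ref$annotation)
  samples <- exp$samples

  # first pass: per-sample track preparation; then one HMM per
  # modification class, fitted on the bins pooled across all samples, so
  # the enriched state is anchored by whichever samples carry genuine
  # signal (wild-type anchors the knockouts)
  preps <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    rd <- exp$reads[exp$reads$sample_id == sid, , drop = FALSE]
    preps[[sid]] <- prepare_sample_tracks(rd, contig_lengths, params)
  }
  classes <- sort(unique(unlist(lapply(preps, function(p)
    names(p$size_factors)))), method = "radix")
  fits <- lapply(stats::setNames(classes, classes), function(cls) {
    pooled <- unlist(lapply(preps, function(p) {
      keep <- vapply(p$cov_e, function(t) t$mod_class == cls, logical(1))
      unlist(p$bins[keep], use.names = FALSE)
    }), use.names = FALSE)
    fit_enrichment_hmm(pooled)
  })

  peaks <- list(); sites <- list(); annotations <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    rd <- exp$reads[exp$reads$sample_id == sid, , drop = FALSE]
    sp <- exp$spike_counts[exp$spike_counts$sample_id == sid, , drop = FALSE]
    res <- call_sample_peaks(rd, contig_lengths, sp, params, sid,
                             hmm_fits = fits, prep = preps[[sid]])
    peaks[[sid]] <- res$peaks

    ino <- res$peaks[res$peaks$mod_class == "inosine", , drop = FALSE]
    cols <- pileup(res$dedup_reads, ref$genome, ino)
    sites[[sid]] <- call_editing_sites(cols, ino)
    annotations[[sid]] <- annotate_peak(res$peaks, index)
  }

  # long table of annotated inosine peaks across samples
  long <- do.call(rbind, lapply(names(peaks), function(sid) {
    pk <- peaks[[sid]]
    ann <- annotations[[sid]]
    ino <- pk[pk$mod_class == "inosine", , drop = FALSE]
    mg <- merge(ann, ino[, c("peak_id", "fold_enrichment")], by = "peak_id")
    if (nrow(mg) == 0) return(NULL)
    mg$sample_id <- sid
    mg$condition <- samples$condition[samples$sample_id == sid]
    mg
  }))

  gsm <- NULL; dependency <- NULL; clusters <- NULL
  if (!is.null(long) && nrow(long) > 0) {
    gsm <- gene_scores(long, samples)
    cs <- gsm$condition_scores
    if (all(c("WT", "p150KO") %in% colnames(cs))) {
      dko <- if ("dKO" %in% colnames(cs)) cs[, "dKO"] else 0
      dependency <- cbind(
        data.frame(gene_id = rownames(cs), stringsAsFactors = FALSE),
        classify_dependency(cs[, "WT"], cs[, "p150KO"], dko))
    }
    if (nrow(gsm$scores) >= max(2, n_clusters)) {
      clusters <- cluster_gene_scores(gsm, n_clusters)
    }
  }

  # per-sample inosine peak counts and reductions vs the first condition
  counts <- lapply(split(samples$sample_id, samples$condition), function(ids) {
    vapply(ids, function(sid)
      sum(peaks[[sid]]$mod_class == "inosine"), numeric(1))
  })
  counts <- counts[unique(samples$condition)]
  reductions <- if (length(counts) >= 2 && mean(counts[[1]]) > 0) {
    reduction_summary(counts, reference = unique(samples$condition)[1])
  } else {
    NULL
  }

  wt_ids <- samples$sample_id[samples$condition == unique(samples$condition)[1]]
  common_wt <- if (length(wt_ids) >= 2) {
    common_genes(lapply(wt_ids, function(sid) {
      ann <- annotations[[sid]]
      ino_ids <- peaks[[sid]]$peak_id[peaks[[sid]]$mod_class == "inosine"]
      unique(ann$gene_id[ann$peak_id %in% ino_ids & ann$gene_id != ""])
    }))
  } else {
    NULL
  }

  region_counts <- region_distribution(do.call(rbind, annotations))

  list(samples = samples, peaks = peaks, sites = sites,
       annotations = annotations, gene_scores = gsm,
       dependency = dependency, reductions = reductions,
       common_wt_genes = common_wt, clusters = clusters,
       region_counts = region_counts, feature_index = index,
       peak_counts = counts)
}

#' Run the full synthetic pipeline from a configuration
#'
#' Convenience wrapper: [simulate_reference()], [simulate_experiment()],
#' [run_pipeline()], and optionally [write_results()].
#'
#' @param config a [sim_config()].
#' @param params a [peak_params()].
#' @param outdir optional output directory for on-disk results.
#' @param n_clusters passed to [run_pipeline()].
#' @return the [run_pipeline()] result, with `ref` and `exp` attached.
#' @export
run_synthetic_pipeline <- function(config, params = peak_params(),
                                   outdir = NULL, n_clusters = 4L) {
  ref <- simulate_reference(config)
  exp <- simulate_experiment(config, ref$genome, ref$annotation)
  res <- run_pipeline(exp, ref, params, n_clusters)
  res$ref <- ref
  res$exp <- exp
  if (!is.null(outdir)) write_results(res, outdir)
  res
}

#' Write pipeline results to disk
#'
#' Per sample: peaks as BED6+3 (`name` = modification class, `score` =
#' `min(1000, round(10 q))`, extra columns fold enrichment, q-score, max
#' depth), editing sites as VCF v4.2 plus a TSV mirror, annotations as
#' TSV. Across samples: dependency table TSV, cluster assignments, and a
#' JSON summary (region distribution, category counts, reductions).
#'
#' @param res a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of paths written.
#' @export
write_results <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  clens <- if (!is.null(res$ref)) {
    stats::setNames(Biostrings::width(res$ref$genome),
                    names(res$ref$genome))
  } else {
    NULL
  }
  for (sid in names(res$peaks)) {
    pb <- file.path(outdir, sprintf("%s_peaks.bed", sid))
    write_peaks_bed(res$peaks[[sid]], pb)
    sv <- file.path(outdir, sprintf("%s_sites.vcf", sid))
    write_sites_vcf(res$sites[[sid]], sv, sample_name = sid,
                    contig_lengths = clens)
    st <- file.path(outdir, sprintf("%s_sites.tsv", sid))
    write_sites_tsv(res$sites[[sid]], st)
    at <- file.path(outdir, sprintf("%s_annotation.tsv", sid))
    write_tsv_stable(res$annotations[[sid]], at)
    paths <- c(paths, pb, sv, st, at)
  }
  if (!is.null(res$dependency)) {
    dp <- file.path(outdir, "dependency.tsv")
    dep <- res$dependency
    for (cc in c("wt_score", "p150ko_score", "dko_score", "ratio")) {
      dep[[cc]] <- fmt_num(dep[[cc]], 4)
    }
    write_tsv_stable(dep, dp)
    paths <- c(paths, dp)
  }
  if (!is.null(res$clusters)) {
    cp <- file.path(outdir, "clusters.txt")
    writeLines(sprintf("%s\t%d", names(res$clusters), res$clusters), cp)
    paths <- c(paths, cp)
  }
  sp <- file.path(outdir, "summary.json")
  summary <- list(
    region_distribution = as.list(res$region_counts),
    reductions = if (!is.null(res$reductions)) as.list(res$reductions),
    category_counts = if (!is.null(res$dependency)) {
      as.list(table(res$dependency$category))
    },
    n_common_wt_genes = if (!is.null(res$common_wt_genes)) {
      length(res$common_wt_genes)
    }
  )
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths <- c(paths, sp)
  invisible(paths)
}

#' Write peaks as BED6+3
#'
#' Columns: chrom, 0-based start, end, name (modification class), score
#' (`min(1000, round(10 q))`), strand, fold enrichment, q-score, max
#' enrichment depth.
#'
#' @param peaks scored peak data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_peaks_bed <- function(peaks, path) {
  lines <- character(0)
  if (nrow(peaks) > 0) {
    lines <- sprintf(
      "%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%d",
      peaks$contig, peaks$start0, peaks$end0, peaks$mod_class,
      pmin(1000L, as.integer(round(10 * peaks$q_score))), peaks$strand,
      fmt_num(peaks$fold_enrichment, 4), fmt_num(peaks$q_score, 2),
      peaks$max_depth)
  }
  writeLines(lines, path)
  invisible(path)
}
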