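#' Simulate a paired enrichment/control experiment with planted truth
#'
#' Generates mapped single-end reads for every condition x replicate, in
#' both an enrichment library (background plus planted peak signal) and a
#' non-enriched solution-control library (background only), together with
#' spike-in count tables and a truth table of planted peaks, editing sites
#' and gene dependency categories.
#'
#' Coverage model: each (modification class, strand) track receives Poisson
#' background at `background_depth` reads/base; a planted peak of fold `f`
#' adds reads over its interval so that expected enrichment depth is
#' `f * background_depth`, scaled per condition by the gene's dependency
#' category (a scaling of 0 removes the peak entirely). Every read carries
#' the MBC barcode of its modification class and a random UMI. Reads
#' covering a planted editing site carry the edited base (G for a
#' plus-strand site, C on the reference-forward strand for a minus-strand
#' site) with probability equal to the site's per-condition realized rate.
#'
#' @param config a [sim_config()] object.
#' @param genome,annotation from [simulate_reference()] run on the same
#'   config.
#' @return list with elements:
#'   * `reads`: data.frame of mapped reads (columns `read_id`, `sample_id`,
#'     `condition`, `replicate`, `library`, `contig`, `pos0`, `strand`,
#'     `length`, `mbc_class`, `umi`, `overrides`); `overrides` encodes
#'     base-at-site substitutions as `"pos0:BASE"` entries joined by `";"`.
#'   * `spike_counts`: per-sample spike recovery table.
#'   * `truth`: list of `peaks`, `sites`, `gene_categories` data.frames.
#'   * `samples`: sample sheet (sample_id, condition, replicate).
#' @export
simulate_experiment <- function(config, genome, annotation) {
  validate_sim_config(config)
  stopifnot(inherits(genome, "DNAStringSet"),
            inherits(annotation, "GRanges"))
  with_seed(stage_seed(config$seed, 22L), {
    truth <- plant_truth(config, genome, annotation)
    samples <- expand.grid(
      replicate = seq_len(config$n_replicates),
      condition = config$conditions,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )[, c("condition", "replicate")]
    samples$sample_id <- sprintf("%s_rep%d", samples$condition, samples$replicate)

    read_tabs <- list()
    spike_tabs <- list()
    for (i in seq_len(nrow(samples))) {
      smp <- samples[i, ]
      rd <- sample_reads(config, genome, truth, smp)
      rd <- apply_edits(config, rd, truth, smp$condition)
      read_tabs[[i]] <- rd
      spike_tabs[[i]] <- sample_spike_counts(config, smp)
    }
    reads <- do.call(rbind, read_tabs)
    rownames(reads) <- NULL
    spike_counts <- do.call(rbind, spike_tabs)
    rownames(spike_counts) <- NULL
    list(reads = reads, spike_counts = spike_counts, truth = truth,
         samples = samples)
  })
}

# Plant peaks (assigned to genes), dependency categories (for genes hosting
# inosine peaks) and editing sites (adenosines on the gene strand inside
# inosine peaks).
plant_truth <- function(config, genome, annotation) {
  genes <- annotation[annotation$type == "gene"]
  empty_peaks <- data.frame(
    peak_id = character(), contig = character(), start0 = integer(),
    end0 = integer(), strand = character(), mod_class = character(),
    fold = numeric(), gene_id = character(), category = character(),
    stringsAsFactors = FALSE
  )
  empty_sites <- data.frame(
    site_id = character(), contig = character(), pos0 = integer(),
    strand = character(), rate = numeric(), peak_id = character(),
    gene_id = character(), stringsAsFactors = FALSE
  )
  if (config$n_peaks == 0 || length(genes) == 0) {
    empty_full <- cbind(empty_peaks,
                        data.frame(signal_start0 = integer(),
                                   signal_end0 = integer()))
    return(list(peaks = empty_full, sites = empty_sites,
                gene_categories = data.frame(gene_id = character(),
                                             category = character())))
  }

  n_m6a <- round(config$n_peaks * config$m6a_fraction)
  classes <- sample(c(rep("inosine", config$n_peaks - n_m6a),
                      rep("m6a", n_m6a)))
  host <- rep(sample(length(genes)), length.out = config$n_peaks)

  peaks <- empty_peaks
  for (k in seq_len(config$n_peaks)) {
    g <- genes[host[k]]
    g_start0 <- GenomicRanges::start(g) - 1L
    g_end0 <- GenomicRanges::end(g)
    width <- min(sample_range(config$peak_width_range), g_end0 - g_start0)
    # rejection placement: avoid overlapping a peak already on this gene
    placed <- FALSE
    for (try in 1:20) {
      s0 <- g_start0 + sample.int(g_end0 - g_start0 - width + 1L, 1L) - 1L
      e0 <- s0 + width
      prior <- peaks[peaks$gene_id == g$gene_id, , drop = FALSE]
      if (nrow(prior) == 0 || all(e0 <= prior$start0 | s0 >= prior$end0)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) next
    peaks <- rbind(peaks, data.frame(
      peak_id = "", contig = as.character(GenomicRanges::seqnames(g)),
      start0 = s0, end0 = e0,
      strand = as.character(GenomicRanges::strand(g)),
      mod_class = classes[k], fold = sample_real_range(config$fold_enrichment_range),
      gene_id = g$gene_id, category = NA_character_,
      stringsAsFactors = FALSE
    ))
  }
  peaks <- peaks[order(peaks$contig, peaks$start0, method = "radix"), ,
                 drop = FALSE]
  peaks$peak_id <- sprintf("truth_peak_%03d", seq_len(nrow(peaks)))
  # the coverage footprint of a planted peak: fragments carrying any peak
  # base extend read_length - 1 beyond the capture interval on each side,
  # so this is the interval an ideal coverage-level caller would report
  clens <- stats::setNames(Biostrings::width(genome), names(genome))
  ext <- config$read_length - 1L
  peaks$signal_start0 <- pmax(peaks$start0 - ext, 0L)
  peaks$signal_end0 <- pmin(peaks$end0 + ext, clens[peaks$contig])

  # dependency categories for genes that host >= 1 inosine peak
  ino_genes <- sort(unique(peaks$gene_id[peaks$mod_class == "inosine"]),
                    method = "radix")
  cats <- assign_categories(ino_genes, config$category_weights)
  gene_categories <- data.frame(gene_id = ino_genes, category = cats,
                                stringsAsFactors = FALSE)
  peaks$category <- gene_categories$category[match(peaks$gene_id,
                                                   gene_categories$gene_id)]

  # editing sites: gene-strand adenosines inside inosine peaks
  sites <- empty_sites
  ab <- config$editing_rate_dist
  for (k in which(peaks$mod_class == "inosine")) {
    pk <- peaks[k, ]
    seq_chars <- strsplit(as.character(Biostrings::subseq(
      genome[[pk$contig]], pk$start0 + 1L, pk$end0)), "")[[1]]
    target <- if (pk$strand == "+") "A" else "T"
    avail <- which(seq_chars == target) - 1L + pk$start0
    n_sites <- min(sample_range(config$sites_per_peak_range), length(avail))
    if (n_sites == 0) next
    pos <- sort(avail[sample.int(length(avail), n_sites)])
    sites <- rbind(sites, data.frame(
      site_id = "", contig = pk$contig, pos0 = pos, strand = pk$strand,
      rate = stats::rbeta(n_sites, ab[[1]], ab[[2]]),
      peak_id = pk$peak_id, gene_id = pk$gene_id, stringsAsFactors = FALSE
    ))
  }
  if (nrow(sites) > 0) {
    sites <- sites[order(sites$contig, sites$pos0, method = "radix"), ,
                   drop = FALSE]
    sites$site_id <- sprintf("truth_site_%04d", seq_len(nrow(sites)))
    rownames(sites) <- NULL
  }
  rownames(peaks) <- NULL
  list(peaks = peaks, sites = sites, gene_categories = gene_categories)
}

# Largest-remainder apportionment of categories over genes, then shuffled.
assign_categories <- function(gene_ids, weights) {
  k <- length(gene_ids)
  if (k == 0) return(character())
  w <- weights / sum(weights)
  counts <- floor(k * w)
  rem <- k - sum(counts)
  if (rem > 0) {
    frac_order <- order(k * w - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1L
  }
  sample(rep(names(w), counts))
}

condition_scaling <- function(config, category, condition) {
  if (is.na(category)) return(1)  # m6a peaks: unaffected by the KO design
  config$condition_design[[category]][[condition]]
}

# True bead-capture advantage of modified over unmodified species,
# implied by the configured spike set. Planted peak folds are expressed in
# spike-calibrated units, so the raw coverage enrichment planted on the
# genome is 1 + (fold - 1) * phi; dividing the called raw fold by the
# measured spike factor (~phi) recovers the planted value.
spike_truth_factor <- function(config) {
  ss <- config$spike_set
  mean(ss$true_enrichment[ss$modified]) /
    mean(ss$true_enrichment[!ss$modified])
}

# Generate the enrichment and control reads for one sample.
sample_reads <- function(config, genome, truth, smp) {
  rl <- config$read_length
  d0 <- config$background_depth
  classes <- unique(unname(config$mbc_table))
  contigs <- names(genome)
  clens <- Biostrings::width(genome)
  names(clens) <- contigs

  # accumulate plain vectors per chunk; one data.frame per sample
  libs <- ctgs <- stds <- clss <- list()
  poss <- list()
  add_chunk <- function(lib, contig, pos0, strand, mbc_class) {
    n <- length(pos0)
    if (n == 0) return(invisible())
    k <- length(poss) + 1L
    libs[[k]] <<- rep(lib, n)
    ctgs[[k]] <<- rep(contig, n)
    poss[[k]] <<- as.integer(pos0)
    stds[[k]] <<- rep(strand, n)
    clss[[k]] <<- rep(mbc_class, n)
    invisible()
  }

  for (lib in c("enrichment", "control")) {
    # flat Poisson background per (class, strand) track
    for (ctg in contigs) {
      L <- clens[[ctg]]
      if (L < rl) next
      for (cls in classes) {
        for (std in c("+", "-")) {
          n_bg <- stats::rpois(1, d0 * (L - rl + 1) / rl)
          starts <- sample.int(L - rl + 1L, n_bg, replace = TRUE) - 1L
          add_chunk(lib, ctg, starts, std, cls)
        }
      }
    }
    if (lib == "enrichment") {
      # planted peak signal, scaled by the gene's dependency category
      pk <- truth$peaks
      phi <- spike_truth_factor(config)
      for (k in seq_len(nrow(pk))) {
        p <- pk[k, ]
        scale <- condition_scaling(config, p$category, smp$condition)
        if (scale <= 0) next
        width <- p$end0 - p$start0
        W <- width + rl - 1
        lambda <- max(0, (p$fold - 1) * phi * scale * d0 * W / rl)
        n_extra <- stats::rpois(1, lambda)
        if (n_extra == 0) next
        starts <- floor(stats::runif(n_extra, p$start0 - rl + 1, p$end0))
        starts <- pmin(pmax(starts, 0L), clens[[p$contig]] - rl)
        add_chunk(lib, p$contig, starts, p$strand, p$mod_class)
      }
    }
  }
  lib_v <- unlist(libs, use.names = FALSE)
  n <- length(lib_v)
  if (n == 0) return(NULL)
  data.frame(
    read_id = sprintf("%s_%s_%07d", smp$sample_id, substr(lib_v, 1, 3),
                      seq_len(n)),
    sample_id = smp$sample_id, condition = smp$condition,
    replicate = smp$replicate, library = lib_v,
    contig = unlist(ctgs, use.names = FALSE),
    pos0 = unlist(poss, use.names = FALSE),
    strand = unlist(stds, use.names = FALSE), length = rl,
    mbc_class = unlist(clss, use.names = FALSE),
    umi = random_umis(n, config$umi_length),
    overrides = "", stringsAsFactors = FALSE
  )
}

random_umis <- function(n, len) {
  if (n == 0) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Assign edited bases to reads covering planted sites. The realized rate in
# a condition is the planted rate scaled by the gene category's condition
# scaling (editing disappears with the signal in knockout conditions).
apply_edits <- function(config, reads, truth, condition) {
  sites <- truth$sites
  if (nrow(sites) == 0 || nrow(reads) == 0) return(reads)
  cat_of <- truth$gene_categories$category[match(sites$gene_id,
                                                 truth$gene_categories$gene_id)]
  realized <- sites$rate * vapply(cat_of, function(ct)
    condition_scaling(config, ct, condition), numeric(1))

  rd_gr <- GenomicRanges::GRanges(
    reads$contig, IRanges::IRanges(reads$pos0 + 1L, reads$pos0 + reads$length))
  st_gr <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(sites$pos0 + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(st_gr, rd_gr, ignore.strand = TRUE)
  if (length(hits) == 0) return(reads)
  s_idx <- S4Vectors::queryHits(hits)
  r_idx <- S4Vectors::subjectHits(hits)
  edited <- stats::runif(length(hits)) < realized[s_idx]
  if (!any(edited)) return(reads)
  s_idx <- s_idx[edited]
  r_idx <- r_idx[edited]
  alt <- ifelse(sites$strand[s_idx] == "+", "G", "C")
  tok <- sprintf("%d:%s", sites$pos0[s_idx], alt)
  agg <- tapply(tok, r_idx, paste, collapse = ";")
  reads$overrides[as.integer(names(agg))] <- unname(agg)
  reads
}

sample_spike_counts <- function(config, smp) {
  ss <- config$spike_set
  data.frame(
    sample_id = smp$sample_id, condition = smp$condition,
    replicate = smp$replicate, spike_id = ss$spike_id,
    modified = ss$modified,
    count_enriched = stats::rpois(nrow(ss),
                                  config$spike_base_count * ss$true_enrichment),
    count_control = stats::rpois(nrow(ss), config$spike_base_count),
    stringsAsFactors = FALSE
  )
}

#' Write a simulated experiment to disk
#'
#' Writes the mapped-read alignment table, spike counts, sample sheet and
#' truth tables as TSV. Numeric rate/fold columns are formatted with a
#' fixed decimal convention so repeated runs are byte-identical.
#'
#' @param exp result of [simulate_experiment()].
#' @param outdir output directory.
#' @return invisibly, the paths written.
#' @export
write_experiment <- function(exp, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reads = file.path(outdir, "reads.tsv"),
    spikes = file.path(outdir, "spike_counts.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    truth_peaks = file.path(outdir, "truth_peaks.tsv"),
    truth_sites = file.path(outdir, "truth_sites.tsv"),
    truth_genes = file.path(outdir, "truth_gene_categories.tsv")
  )
  write_tsv_stable(reads_out(exp$reads), paths["reads"])
  write_tsv_stable(exp$spike_counts, paths["spikes"])
  write_tsv_stable(exp$samples, paths["samples"])
  tp <- exp$truth$peaks
  tp$fold <- fmt_num(tp$fold, 4)
  write_tsv_stable(tp, paths["truth_peaks"])
  ts <- exp$truth$sites
  ts$rate <- fmt_num(ts$rate, 6)
  write_tsv_stable(ts, paths["truth_sites"])
  write_tsv_stable(exp$truth$gene_categories, paths["truth_genes"])
  invisible(paths)
}

reads_out <- function(reads) {
  reads[, c("read_id", "sample_id", "condition", "replicate", "library",
            "contig", "pos0", "strand", "length", "mbc_class", "umi",
            "overrides")]
}

#' Read a mapped-read alignment table written by [write_experiment()]
#' @param path TSV path.
#' @return data.frame of mapped reads.
#' @export
read_alignment_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE,
                    colClasses = c(overrides = "character"))
}

write_tsv_stable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", eol = "\n")
}
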