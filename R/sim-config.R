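#' Simulation configuration for synthetic enrichment experiments
#'
#' Builds and validates the configuration object consumed by
#' [simulate_reference()] and [simulate_experiment()]. The defaults describe
#' a small but complete modification-enrichment experiment: a multi-contig
#' genome carrying spliced genes, planted inosine and m6A peaks with
#' configurable fold enrichment, per-site A-to-I editing rates drawn from a
#' Beta distribution, Poisson background coverage, spike-in controls with
#' known recovery ratios, and a three-condition knockout design
#' (WT, p150KO, dKO) in which each gene category scales its planted peak
#' intensity per condition.
#'
#' @param seed integer master seed; all randomness in the simulator flows
#'   from it through fixed per-stage offsets, so a fixed seed gives
#'   byte-identical outputs.
#' @param n_contigs number of genomic contigs.
#' @param contig_length length of each contig in bases.
#' @param n_genes number of genes placed across the contigs.
#' @param gene_structure list of inclusive length ranges (2-vectors):
#'   `n_exons_range`, `exon_length_range`, `intron_length_range`,
#'   `utr5_length_range`, `utr3_length_range`. UTRs are carved out of the
#'   terminal exons of protein-coding genes.
#' @param lnc_fraction fraction of genes given biotype `lncRNA`
#'   (single-biotype, non-coding: no CDS/UTR records).
#' @param n_peaks number of planted peaks (each assigned to one gene).
#' @param m6a_fraction fraction of planted peaks of modification class
#'   `m6a`; the rest are `inosine`. m6A peaks are unaffected by the
#'   knockout design, mirroring their stability across conditions.
#' @param peak_width_range planted peak width range, bases.
#' @param fold_enrichment_range planted fold-enrichment range
#'   (dimensionless, relative to background depth).
#' @param editing_rate_dist `c(alpha, beta)` of the Beta distribution from
#'   which each planted site's editing rate is drawn (values in (0,1]).
#' @param sites_per_peak_range number of A-to-I sites planted per inosine
#'   peak (capped by available adenosines in the peak).
#' @param background_depth mean Poisson background coverage per
#'   (modification class, strand) track, reads/base.
#' @param read_length fixed single-end read length, bases.
#' @param umi_length UMI length, bases.
#' @param mbc_table named character vector mapping MBC barcode sequence to
#'   modification class, e.g. `c(ACGT = "inosine", TGCA = "m6a")`.
#' @param spike_set data.frame with columns `spike_id`, `modified`
#'   (logical), `true_enrichment` (recovery ratio of enriched over control
#'   library for that spike).
#' @param spike_base_count expected control-library read count per spike.
#' @param condition_design named list: gene dependency category ->
#'   named numeric vector of per-condition intensity scalings
#'   (names must cover `conditions`). A scaling of 0 removes the planted
#'   signal in that condition; 1 leaves it at full strength.
#' @param category_weights named numeric vector of planting proportions
#'   over the categories in `condition_design`.
#' @param conditions condition names, first must be the reference (WT).
#' @param n_replicates replicates per condition.
#' @param error_rate uniform sequencing-error substitution rate applied to
#'   non-edited bases (default 0: edits are the only substitutions).
#'
#' @return a validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 4, n_peaks = 3)
#' cfg$background_depth
sim_config <- function(seed = 1L,
                       n_contigs = 2L,
                       contig_length = 50000L,
                       n_genes = 12L,
                       gene_structure = list(
                         n_exons_range = c(2L, 4L),
                         exon_length_range = c(150L, 400L),
                         intron_length_range = c(500L, 1000L),
                         utr5_length_range = c(50L, 120L),
                         utr3_length_range = c(100L, 250L)
                       ),
                       lnc_fraction = 0.15,
                       n_peaks = 10L,
                       m6a_fraction = 0.2,
                       peak_width_range = c(120L, 300L),
                       fold_enrichment_range = c(8, 16),
                       editing_rate_dist = c(alpha = 2, beta = 4),
                       sites_per_peak_range = c(4L, 10L),
                       background_depth = 20,
                       read_length = 100L,
                       umi_length = 8L,
                       mbc_table = c(ACGT = "inosine", TGCA = "m6a"),
                       spike_set = data.frame(
                         spike_id = c("spike_mod_1", "spike_mod_2",
                                      "spike_unmod_1", "spike_unmod_2"),
                         modified = c(TRUE, TRUE, FALSE, FALSE),
                         true_enrichment = c(10, 10, 1, 1)
                       ),
                       spike_base_count = 1000,
                       condition_design = list(
                         strong = c(WT = 1, p150KO = 0, dKO = 0),
                         mild = c(WT = 1, p150KO = 0.4, dKO = 0),
                         independent = c(WT = 1, p150KO = 1, dKO = 0),
                         p150KO_specific = c(WT = 0, p150KO = 1, dKO = 0)
                       ),
                       category_weights = c(strong = 0.5, mild = 0.2,
                                            independent = 0.2,
                                            p150KO_specific = 0.1),
                       conditions = c("WT", "p150KO", "dKO"),
                       n_replicates = 2L,
                       error_rate = 0) {
  cfg <- list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length), n_genes = as.integer(n_genes),
    gene_structure = gene_structure, lnc_fraction = lnc_fraction,
    n_peaks = as.integer(n_peaks), m6a_fraction = m6a_fraction,
    peak_width_range = peak_width_range,
    fold_enrichment_range = fold_enrichment_range,
    editing_rate_dist = editing_rate_dist,
    sites_per_peak_range = sites_per_peak_range,
    background_depth = background_depth,
    read_length = as.integer(read_length),
    umi_length = as.integer(umi_length),
    mbc_table = mbc_table, spike_set = spike_set,
    spike_base_count = spike_base_count,
    condition_design = condition_design,
    category_weights = category_weights,
    conditions = conditions, n_replicates = as.integer(n_replicates),
    error_rate = error_rate
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

check_range <- function(r, what, integer_ok = TRUE) {
  if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
    stop(sprintf("configuration error: %s must be a finite [lo, hi] range with lo <= hi", what))
  }
  invisible(r)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_contigs < 1 || cfg$contig_length < 1) {
    stop("configuration error: need at least one contig of positive length")
  }
  if (cfg$n_genes < 0 || cfg$n_peaks < 0) {
    stop("configuration error: n_genes and n_peaks must be non-negative")
  }
  gs <- cfg$gene_structure
  for (nm in c("n_exons_range", "exon_length_range", "intron_length_range",
               "utr5_length_range", "utr3_length_range")) {
    check_range(gs[[nm]], paste0("gene_structure$", nm))
  }
  check_range(cfg$peak_width_range, "peak_width_range")
  check_range(cfg$fold_enrichment_range, "fold_enrichment_range")
  check_range(cfg$sites_per_peak_range, "sites_per_peak_range")
  if (any(cfg$editing_rate_dist <= 0)) {
    stop("configuration error: editing_rate_dist Beta parameters must be positive")
  }
  if (cfg$background_depth <= 0) {
    stop("configuration error: background_depth must be > 0")
  }
  if (cfg$read_length < 1 || cfg$umi_length < 1) {
    stop("configuration error: read_length and umi_length must be >= 1")
  }
  if (is.null(names(cfg$mbc_table)) || any(names(cfg$mbc_table) == "")) {
    stop("configuration error: mbc_table must be a named (barcode -> class) vector")
  }
  if (length(unique(nchar(names(cfg$mbc_table)))) != 1) {
    stop("configuration error: all MBC barcodes must share one length")
  }
  ss <- cfg$spike_set
  if (!all(c("spike_id", "modified", "true_enrichment") %in% names(ss))) {
    stop("configuration error: spike_set needs spike_id, modified, true_enrichment")
  }
  if (nrow(ss) > 0 && (!any(ss$modified) || all(ss$modified))) {
    stop("configuration error: spike_set needs >= 1 modified and >= 1 unmodified spike")
  }
  if (!identical(sort(names(cfg$category_weights)),
                 sort(names(cfg$condition_design)))) {
    stop("configuration error: category_weights must name the condition_design categories")
  }
  for (cat in names(cfg$condition_design)) {
    sc <- cfg$condition_design[[cat]]
    if (!all(cfg$conditions %in% names(sc))) {
      stop(sprintf("configuration error: condition_design$%s must name every condition", cat))
    }
    if (any(sc < 0)) stop("configuration error: condition scalings must be >= 0")
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) {
    stop("configuration error: error_rate must be in [0, 1)")
  }
  if (cfg$n_replicates < 1) stop("configuration error: n_replicates >= 1")
  invisible(cfg)
}
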