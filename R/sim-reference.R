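#' Simulate a reference genome and gene annotation
#'
#' Generates random genomic contigs, short spike-in contigs, and a gene
#' annotation with spliced transcripts. Protein-coding genes carry CDS and
#' UTR records (UTRs carved from terminal exons); a configurable fraction
#' of genes are non-coding with `gene_biotype = "lncRNA"`. Introns are the
#' exact gaps between consecutive exons and are derivable from the emitted
#' exon records.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `genome` (named [Biostrings::DNAStringSet]),
#'   `spikes` (DNAStringSet, one short contig per spike), and `annotation`
#'   (a [GenomicRanges::GRanges] with GTF-style `type`, `gene_id`,
#'   `transcript_id`, `gene_biotype` metadata columns; coordinates 1-based
#'   inclusive as on disk).
#' @export
#' @examples
#' ref <- simulate_reference(sim_config(seed = 3, n_genes = 2, n_peaks = 2))
#' names(ref$genome)
simulate_reference <- function(config) {
  validate_sim_config(config)
  with_seed(stage_seed(config$seed, 11L), {
    genome <- random_contigs(config$n_contigs, config$contig_length, "contig")
    spikes <- random_contigs(nrow(config$spike_set), 200L,
                             prefix = NULL, names = config$spike_set$spike_id)
    annotation <- simulate_genes(config)
    list(genome = genome, spikes = spikes, annotation = annotation)
  })
}

random_contigs <- function(n, len, prefix, names = NULL) {
  if (n == 0) return(Biostrings::DNAStringSet())
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names %||% sprintf("%s_%d", prefix, seq_len(n))
  out
}

# Lay out n_genes across contigs (round-robin), each gene a single
# transcript of alternating exons/introns. Returns a GTF-shaped GRanges.
simulate_genes <- function(config) {
  gs <- config$gene_structure
  margin <- 300L
  n <- config$n_genes
  empty <- GenomicRanges::GRanges(
    seqnames = character(), ranges = IRanges::IRanges(), strand = character(),
    type = character(), gene_id = character(), transcript_id = character(),
    gene_biotype = character()
  )
  if (n == 0) return(empty)

  contig_of <- rep(sprintf("contig_%d", seq_len(config$n_contigs)), length.out = n)
  n_lnc <- floor(config$lnc_fraction * n)
  biotype <- rep("protein_coding", n)
  if (n_lnc > 0) biotype[sample.int(n, n_lnc)] <- "lncRNA"
  strand <- sample(c("+", "-"), n, replace = TRUE)

  # draw structures first so per-contig space requirements are known
  structures <- lapply(seq_len(n), function(i) {
    n_ex <- sample_range(gs$n_exons_range)
    exon_len <- sample_range(gs$exon_length_range, n_ex)
    intron_len <- if (n_ex > 1) sample_range(gs$intron_length_range, n_ex - 1L) else integer()
    list(exon_len = exon_len, intron_len = intron_len,
         span = sum(exon_len) + sum(intron_len))
  })

  recs <- list()
  for (ctg in unique(contig_of)) {
    idx <- which(contig_of == ctg)
    spans <- vapply(structures[idx], `[[`, numeric(1), "span")
    need <- sum(spans) + (length(idx) + 1L) * margin
    if (need > config$contig_length) {
      stop(sprintf(
        "configuration error: contig %s (length %d) too short to host %d genes (need %d bases)",
        ctg, config$contig_length, length(idx), need))
    }
    gap <- floor((config$contig_length - sum(spans)) / (length(idx) + 1L))
    cursor <- gap  # 0-based start of next gene
    for (i in idx) {
      st <- structures[[i]]
      gene_id <- sprintf("gene_%03d", i)
      recs[[length(recs) + 1L]] <-
        gene_records(gene_id, ctg, cursor, strand[i], biotype[i], st, gs)
      cursor <- cursor + st$span + gap
    }
  }
  out <- do.call(c, recs)
  names(out) <- NULL
  out
}

# Build gene/transcript/exon/CDS/UTR records for one gene starting at
# 0-based position `start0`. Emits 1-based inclusive coordinates (GTF).
gene_records <- function(gene_id, contig, start0, strand, biotype, st, gs) {
  n_ex <- length(st$exon_len)
  exon_start0 <- start0 + c(0, cumsum(st$exon_len[-n_ex] + st$intron_len))
  exon_end0 <- exon_start0 + st$exon_len  # half-open
  tx_id <- paste0(gene_id, ".t1")

  mk <- function(type, s0, e0, phase = NA_integer_) {
    GenomicRanges::GRanges(
      seqnames = contig,
      ranges = IRanges::IRanges(start = s0 + 1L, end = e0),
      strand = strand, type = type, gene_id = gene_id,
      transcript_id = if (type == "gene") NA_character_ else tx_id,
      gene_biotype = biotype, phase = phase
    )
  }

  recs <- list(
    mk("gene", start0, start0 + st$span),
    mk("transcript", start0, start0 + st$span),
    mk("exon", exon_start0, exon_end0)
  )

  if (biotype == "protein_coding") {
    # UTR lengths bounded so each terminal exon keeps >= 1 CDS base
    u5 <- min(sample_range(gs$utr5_length_range), st$exon_len[1] - 1L,
              st$exon_len[n_ex] - 1L)
    u3 <- min(sample_range(gs$utr3_length_range), st$exon_len[n_ex] - 1L,
              st$exon_len[1] - 1L)
    if (n_ex == 1L) u3 <- max(0L, min(u3, st$exon_len[1] - u5 - 1L))
    cds_s0 <- exon_start0
    cds_e0 <- exon_end0
    if (strand == "+") {
      cds_s0[1] <- cds_s0[1] + u5
      cds_e0[n_ex] <- cds_e0[n_ex] - u3
      utr5 <- mk("five_prime_utr", exon_start0[1], exon_start0[1] + u5)
      utr3 <- mk("three_prime_utr", exon_end0[n_ex] - u3, exon_end0[n_ex])
    } else {
      # transcript 5' end is the genomic right end
      cds_e0[n_ex] <- cds_e0[n_ex] - u5
      cds_s0[1] <- cds_s0[1] + u3
      utr5 <- mk("five_prime_utr", exon_end0[n_ex] - u5, exon_end0[n_ex])
      utr3 <- mk("three_prime_utr", exon_start0[1], exon_start0[1] + u3)
    }
    # GTF frame: bases of the codon completed at the start of each CDS
    # piece, walking pieces in transcript (5'->3') order
    cds_len <- cds_e0 - cds_s0
    ord <- if (strand == "+") seq_along(cds_len) else rev(seq_along(cds_len))
    cum_before <- cumsum(c(0L, cds_len[ord]))[seq_along(cds_len)]
    phase <- integer(length(cds_len))
    phase[ord] <- (3L - cum_before %% 3L) %% 3L
    recs <- c(recs, list(mk("CDS", cds_s0, cds_e0, phase = phase)),
              if (u5 > 0) list(utr5), if (u3 > 0) list(utr3))
  }
  do.call(c, recs)
}

#' Write simulated reference files
#'
#' Writes the genome and spike contigs as FASTA and the annotation as GTF.
#'
#' @param ref result of [simulate_reference()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reference <- function(ref, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(outdir, "genome.fa"),
    spikes = file.path(outdir, "spikes.fa"),
    annotation = file.path(outdir, "annotation.gtf")
  )
  Biostrings::writeXStringSet(ref$genome, paths["genome"])
  Biostrings::writeXStringSet(ref$spikes, paths["spikes"])
  if (length(ref$annotation) == 0) {
    writeLines("#gtf", paths["annotation"])  # valid empty annotation
  } else {
    rtracklayer::export(ref$annotation, paths["annotation"], format = "gtf")
  }
  invisible(paths)
}
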