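#' Build a feature index from a gene annotation
#'
#' Derives the interval-to-feature lookup used to classify peaks:
#' per-transcript introns are the exact gaps between consecutive exons;
#' 5'/3' UTRs are exon-minus-CDS pieces oriented by strand; exonic
#' intervals of lncRNA-biotype genes carry class `lncRNA`; for coding
#' transcripts the CDS carries class `exon` (the coding classes take
#' precedence over the generic exon where a CDS exists); exons of
#' transcripts without CDS (and without lncRNA biotype) stay class `exon`.
#'
#' @param annotation a GTF-style [GenomicRanges::GRanges] (as read by
#'   `rtracklayer::import` or built by [simulate_reference()]) with
#'   `type`, `gene_id`, `transcript_id`, `gene_biotype` columns.
#' @return a `GRanges` of feature intervals with metadata columns
#'   `gene_id` and `feature_class`.
#' @export
build_feature_index <- function(annotation) {
  stopifnot(inherits(annotation, "GRanges"))
  need <- c("type", "gene_id", "transcript_id")
  if (!all(need %in% names(S4Vectors::mcols(annotation)))) {
    stop("annotation must carry type, gene_id and transcript_id")
  }
  if (!"gene_biotype" %in% names(S4Vectors::mcols(annotation))) {
    annotation$gene_biotype <- "protein_coding"
  }
  exons <- annotation[annotation$type == "exon"]
  cds <- annotation[annotation$type == "CDS"]
  if (length(exons) == 0) {
    return(GenomicRanges::GRanges(gene_id = character(),
                                  feature_class = character()))
  }

  ex_by_tx <- S4Vectors::split(exons, exons$transcript_id)
  pieces <- list()
  add <- function(gr, gene_id, class) {
    if (length(gr) == 0) return(invisible())
    gr <- GenomicRanges::granges(gr)
    S4Vectors::mcols(gr) <- NULL
    gr$gene_id <- gene_id
    gr$feature_class <- class
    pieces[[length(pieces) + 1L]] <<- gr
    invisible()
  }

  for (tx in names(ex_by_tx)) {
    ex <- ex_by_tx[[tx]]
    ex <- ex[order(GenomicRanges::start(ex))]
    if (length(ex) > 1 &&
        any(GenomicRanges::start(ex)[-1] <=
              GenomicRanges::end(ex)[-length(ex)])) {
      stop(sprintf("transcript %s has overlapping exons", tx))
    }
    gid <- ex$gene_id[1]
    strand <- as.character(GenomicRanges::strand(ex))[1]
    biotype <- ex$gene_biotype[1]

    # introns: exact inter-exon gaps
    if (length(ex) > 1) {
      intr <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(ex)[1],
        IRanges::IRanges(GenomicRanges::end(ex)[-length(ex)] + 1L,
                         GenomicRanges::start(ex)[-1] - 1L),
        strand = strand)
      add(intr, gid, "intron")
    }

    if (identical(biotype, "lncRNA")) {
      add(ex, gid, "lncRNA")
      next
    }
    tx_cds <- cds[cds$transcript_id == tx]
    if (length(tx_cds) == 0) {
      add(ex, gid, "exon")
      next
    }
    # coding: CDS intervals class as exon; exon-minus-CDS pieces are UTR,
    # sided by strand relative to the CDS span
    add(tx_cds, gid, "exon")
    utr <- GenomicRanges::setdiff(GenomicRanges::granges(ex),
                                  GenomicRanges::granges(tx_cds),
                                  ignore.strand = FALSE)
    if (length(utr) > 0) {
      cds_lo <- min(GenomicRanges::start(tx_cds))
      cds_hi <- max(GenomicRanges::end(tx_cds))
      before <- GenomicRanges::end(utr) < cds_lo
      after <- GenomicRanges::start(utr) > cds_hi
      five <- if (strand == "-") after else before
      three <- if (strand == "-") before else after
      add(utr[five], gid, "five_prime_utr")
      add(utr[three], gid, "three_prime_utr")
    }
  }
  out <- do.call(c, pieces)
  names(out) <- NULL
  sort(out, ignore.strand = TRUE)
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    peaks$contig,
    IRanges::IRanges(peaks$start0 + 1L, peaks$end0),
    strand = peaks$strand)
}

#' Annotate peaks with overlapping gene features
#'
#' Reports every (gene, feature class) pair whose indexed interval
#' overlaps a peak by at least one base on the same strand. Peaks with no
#' overlap are reported with an empty gene and class `unannotated`.
#'
#' @param peaks peak data.frame with `peak_id`, `contig`, `start0`,
#'   `end0`, `strand` (plus any score columns, passed through by
#'   `peak_id`).
#' @param index feature index from [build_feature_index()].
#' @return data.frame `peak_id`, `gene_id`, `feature_class`, one row per
#'   distinct pair, in peak order.
#' @export
annotate_peak <- function(peaks, index) {
  if (nrow(peaks) == 0) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      feature_class = character(), stringsAsFactors = FALSE))
  }
  gr <- peaks_to_granges(peaks)
  hits <- GenomicRanges::findOverlaps(gr, index, minoverlap = 1L,
                                      ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ann <- data.frame(peak_id = peaks$peak_id[qh],
                    gene_id = index$gene_id[sh],
                    feature_class = index$feature_class[sh],
                    stringsAsFactors = FALSE)
  ann <- unique(ann)
  missing <- setdiff(peaks$peak_id, ann$peak_id)
  if (length(missing) > 0) {
    ann <- rbind(ann, data.frame(peak_id = missing, gene_id = "",
                                 feature_class = "unannotated",
                                 stringsAsFactors = FALSE))
  }
  ann <- ann[order(match(ann$peak_id, peaks$peak_id), ann$gene_id,
                   ann$feature_class, method = "radix"), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Regional distribution of modified genes
#'
#' For each feature class, the number of distinct genes with at least one
#' peak annotated to that class. A gene modified in several regions counts
#' once per region, so the class counts can sum to more than the number of
#' distinct genes.
#'
#' @param annotated_peaks data.frame from [annotate_peak()].
#' @param classes classes to report (zero-filled when absent).
#' @return named integer vector of gene counts per class.
#' @export
region_distribution <- function(annotated_peaks,
                                classes = c("exon", "intron",
                                            "five_prime_utr",
                                            "three_prime_utr", "lncRNA")) {
  ann <- annotated_peaks[annotated_peaks$gene_id != "", , drop = FALSE]
  counts <- stats::setNames(integer(length(classes)), classes)
  if (nrow(ann) > 0) {
    tab <- tapply(ann$gene_id, ann$feature_class,
                  function(g) length(unique(g)))
    found <- intersect(names(tab), classes)
    counts[found] <- as.integer(tab[found])
    extra <- setdiff(names(tab), classes)
    if (length(extra) > 0) {
      counts <- c(counts, stats::setNames(as.integer(tab[extra]), extra))
    }
  }
  counts
}
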