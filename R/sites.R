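#' Pileup base counts over regions
#'
#' Per-column base counts from mapped reads, split by read strand. A
#' read's base at a position is the reference base unless the read carries
#' a base override (`"pos0:BASE"` entries in its `overrides` column, the
#' alignment-table encoding of observed substitutions). Column depth is
#' capped at `max_depth` reads: when coverage exceeds the cap, the first
#' `max_depth` reads in (start, read_id) order are counted.
#'
#' @param reads mapped-read data.frame (deduplicated).
#' @param genome named [Biostrings::DNAStringSet].
#' @param regions data.frame with `contig`, `start0`, `end0` (0-based
#'   half-open); overlapping regions are counted once per distinct column.
#' @param max_depth per-column read cap (default 20000).
#' @return data.frame of pileup columns: `contig`, `pos0`, `ref_base`,
#'   `A_fwd` ... `T_fwd`, `A_rev` ... `T_rev`, `depth`.
#' @export
pileup <- function(reads, genome, regions, max_depth = 20000L) {
  stopifnot(all(c("contig", "start0", "end0") %in% names(regions)))
  bases <- c("A", "C", "G", "T")
  cols <- c(paste0(bases, "_fwd"), paste0(bases, "_rev"))
  empty <- stats::setNames(
    data.frame(contig = character(), pos0 = integer(),
               ref_base = character(),
               matrix(integer(), 0, 8), depth = integer(),
               stringsAsFactors = FALSE),
    c("contig", "pos0", "ref_base", cols, "depth"))
  if (nrow(regions) == 0 || nrow(reads) == 0) return(empty)
  bad <- !(regions$contig %in% names(genome)) | regions$start0 < 0 |
    regions$end0 > Biostrings::width(genome)[match(regions$contig,
                                                   names(genome))]
  if (any(bad)) stop("region outside the genome")

  out <- list()
  for (ri in seq_len(nrow(regions))) {
    rg <- regions[ri, ]
    pos <- rg$start0:(rg$end0 - 1L)
    refc <- strsplit(as.character(
      Biostrings::subseq(genome[[rg$contig]], rg$start0 + 1L, rg$end0)),
      "")[[1]]
    on_ctg <- which(reads$contig == rg$contig &
                      reads$pos0 < rg$end0 &
                      reads$pos0 + reads$length > rg$start0)
    counts <- matrix(0L, length(pos), 8L, dimnames = list(NULL, cols))
    if (length(on_ctg) > 0) {
      rr <- reads[on_ctg, , drop = FALSE]
      # per-strand coverage -> default (reference-base) counts
      for (std in c("+", "-")) {
        sfx <- if (std == "+") "_fwd" else "_rev"
        si <- rr$strand == std
        if (!any(si)) next
        cov <- IRanges::coverage(
          IRanges::IRanges(rr$pos0[si] + 1L,
                           pmin(rr$pos0[si] + rr$length[si], rg$end0)),
          width = rg$end0)
        covv <- as.integer(cov)[pos + 1L]
        for (b in bases) {
          hit <- refc == b
          counts[hit, paste0(b, sfx)] <- covv[hit]
        }
      }
      # apply overrides: move one count from the reference base to the
      # observed base
      has_ov <- which(rr$overrides != "")
      if (length(has_ov) > 0) {
        toks <- strsplit(rr$overrides[has_ov], ";", fixed = TRUE)
        n_tok <- lengths(toks)
        flat <- unlist(toks, use.names = FALSE)
        op <- as.integer(sub(":.*", "", flat))
        ob <- sub(".*:", "", flat)
        ostrand <- rep(rr$strand[has_ov], n_tok)
        in_rg <- op >= rg$start0 & op < rg$end0
        for (j in which(in_rg)) {
          row <- op[j] - rg$start0 + 1L
          sfx <- if (ostrand[j] == "+") "_fwd" else "_rev"
          rb <- refc[row]
          if (ob[j] == rb) next
          counts[row, paste0(rb, sfx)] <- counts[row, paste0(rb, sfx)] - 1L
          counts[row, paste0(ob[j], sfx)] <- counts[row, paste0(ob[j], sfx)] + 1L
        }
      }
      depth <- rowSums(counts)
      over <- which(depth > max_depth)
      if (length(over) > 0) {
        # exact recount of the capped columns from the first max_depth
        # covering reads in (start, read_id) order
        ord <- order(rr$pos0, rr$read_id, method = "radix")
        rs <- rr[ord, , drop = FALSE]
        ov_map <- read_override_map(rs)
        for (row in over) {
          p <- pos[row]
          cov_i <- which(rs$pos0 <= p & rs$pos0 + rs$length > p)
          cov_i <- cov_i[seq_len(max_depth)]
          cvec <- stats::setNames(integer(8L), cols)
          for (k in cov_i) {
            b <- ov_map[[rs$read_id[k]]][[as.character(p)]] %||% refc[row]
            sfx <- if (rs$strand[k] == "+") "_fwd" else "_rev"
            cvec[paste0(b, sfx)] <- cvec[paste0(b, sfx)] + 1L
          }
          counts[row, ] <- cvec
        }
      }
    }
    df <- data.frame(contig = rg$contig, pos0 = pos, ref_base = refc,
                     counts, depth = as.integer(rowSums(counts)),
                     stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- df
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("contig", "pos0")]), , drop = FALSE]
  res <- res[order(res$contig, res$pos0, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# read_id -> (pos as character -> base) nested override lookup
read_override_map <- function(reads) {
  m <- list()
  for (i in which(reads$overrides != "")) {
    toks <- strsplit(reads$overrides[i], ";", fixed = TRUE)[[1]]
    inner <- list()
    for (t in toks) {
      kv <- strsplit(t, ":", fixed = TRUE)[[1]]
      inner[[kv[1]]] <- kv[2]
    }
    m[[reads$read_id[i]]] <- inner
  }
  m
}

#' Call A-to-I editing sites inside inosine peaks
#'
#' A pileup column is reported as an editing site when all four clauses
#' hold: (a) its position lies inside an inosine-class peak; (b) the
#' reference base matches the peak's gene-strand context — `A` with `G`
#' alternates on a plus-strand peak, `T` with `C` alternates (the
#' reference-forward image of A-to-G) on a minus-strand peak; (c) column
#' depth exceeds `min_depth_exclusive` (strictly); (d) the variant rate
#' (alternate reads over total column depth, both read strands counted
#' jointly) is at least `min_rate`.
#'
#' @param columns pileup columns from [pileup()].
#' @param peaks peak data.frame; only rows with `mod_class == "inosine"`
#'   are used. Needs `peak_id`, `contig`, `start0`, `end0`, `strand`.
#' @param min_rate minimum variant rate (default 0.10).
#' @param min_depth_exclusive depth must be strictly greater than this
#'   (default 5).
#' @return data.frame of editing sites sorted by (contig, pos0): `contig`,
#'   `pos0`, `strand`, `depth`, `ref_count`, `alt_count`, `rate`,
#'   `peak_id`.
#' @export
call_editing_sites <- function(columns, peaks, min_rate = 0.10,
                               min_depth_exclusive = 5L) {
  empty <- data.frame(contig = character(), pos0 = integer(),
                      strand = character(), depth = integer(),
                      ref_count = integer(), alt_count = integer(),
                      rate = numeric(), peak_id = character(),
                      stringsAsFactors = FALSE)
  ino <- peaks[peaks$mod_class == "inosine", , drop = FALSE]
  if (nrow(columns) == 0 || nrow(ino) == 0) return(empty)

  col_gr <- GenomicRanges::GRanges(
    columns$contig, IRanges::IRanges(columns$pos0 + 1L, width = 1L))
  pk_gr <- GenomicRanges::GRanges(
    ino$contig, IRanges::IRanges(ino$start0 + 1L, ino$end0))
  hits <- GenomicRanges::findOverlaps(col_gr, pk_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # the peak's gene strand sets the expected reference base: A (alt G) on
  # plus, T (alt C, the reference-forward image) on minus
  valid <- ifelse(ino$strand[sh] == "+",
                  columns$ref_base[qh] == "A",
                  columns$ref_base[qh] == "T")
  qh <- qh[valid]; sh <- sh[valid]
  first <- !duplicated(qh)
  qh <- qh[first]; sh <- sh[first]
  if (length(qh) == 0) return(empty)

  plus <- ino$strand[sh] == "+"
  alt <- ifelse(plus, columns$G_fwd[qh] + columns$G_rev[qh],
                columns$C_fwd[qh] + columns$C_rev[qh])
  refn <- ifelse(plus, columns$A_fwd[qh] + columns$A_rev[qh],
                 columns$T_fwd[qh] + columns$T_rev[qh])
  depth <- columns$depth[qh]
  rate <- ifelse(depth > 0, alt / depth, 0)
  keep <- depth > min_depth_exclusive & rate >= min_rate
  res <- data.frame(contig = columns$contig[qh][keep],
                    pos0 = columns$pos0[qh][keep],
                    strand = ino$strand[sh][keep],
                    depth = as.integer(depth[keep]),
                    ref_count = as.integer(refn[keep]),
                    alt_count = as.integer(alt[keep]),
                    rate = rate[keep],
                    peak_id = ino$peak_id[sh][keep],
                    stringsAsFactors = FALSE)
  res <- res[order(res$contig, res$pos0, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Editing-site density of a peak
#'
#' Sites per 100 bases: `100 * n_sites / (end - start)`.
#'
#' @param sites editing-site data.frame (rows belonging to `peak`).
#' @param peak a single peak row with `start0`, `end0`.
#' @return numeric density.
#' @export
editing_density <- function(sites, peak) {
  width <- peak$end0 - peak$start0
  if (length(width) != 1 || width <= 0) stop("peak must have positive width")
  100 * nrow(sites) / width
}

#' Write editing sites as VCF v4.2
#'
#' One record per site: REF/ALT are `A`/`G` for plus-strand sites and
#' `T`/`C` for minus-strand sites (reference-forward representation); POS
#' is 1-based. INFO carries `PEAK_ID`, `STRAND`, `EDIT_RATE`; the single
#' sample's FORMAT is `DP:AD` with `AD` as ref,alt counts.
#'
#' @param sites editing-site data.frame from [call_editing_sites()].
#' @param path output file.
#' @param sample_name sample column name.
#' @param contig_lengths optional named vector for `##contig` headers.
#' @return invisibly, `path`.
#' @export
write_sites_vcf <- function(sites, path, sample_name = "sample",
                            contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=editpeaks",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##INFO=<ID=PEAK_ID,Number=1,Type=String,Description=\"Containing inosine peak\">",
    "##INFO=<ID=STRAND,Number=1,Type=String,Description=\"Gene strand of the edit\">",
    "##INFO=<ID=EDIT_RATE,Number=1,Type=Float,Description=\"Variant rate (alt reads over column depth)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Column depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read counts\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t")
  )
  body <- character(0)
  if (nrow(sites) > 0) {
    ref <- ifelse(sites$strand == "+", "A", "T")
    alt <- ifelse(sites$strand == "+", "G", "C")
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tPEAK_ID=%s;STRAND=%s;EDIT_RATE=%s\tDP:AD\t%d:%d,%d",
      sites$contig, sites$pos0 + 1L, ref, alt, sites$peak_id, sites$strand,
      fmt_num(sites$rate, 4), sites$depth, sites$ref_count, sites$alt_count)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write editing sites as TSV
#' @param sites editing-site data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sites_tsv <- function(sites, path) {
  out <- sites
  out$rate <- fmt_num(out$rate, 4)
  write_tsv_stable(out, path)
  invisible(path)
}
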