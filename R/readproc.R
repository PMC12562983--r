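#' Barcode layout for modification-encoded reads
#'
#' Reads begin with a modification barcode (MBC) identifying the captured
#' modification class, followed by a unique molecular identifier (UMI),
#' followed by the cDNA insert. The exact MBC length and code table are
#' assay-specific and therefore configurable.
#'
#' @param mbc_table named character vector, barcode sequence -> class.
#' @param umi_length UMI length in bases.
#' @return list of class `barcode_layout` with `mbc_length`, `umi_length`,
#'   `mbc_table`.
#' @export
barcode_layout <- function(mbc_table = c(ACGT = "inosine", TGCA = "m6a"),
                           umi_length = 8L) {
  if (is.null(names(mbc_table)) || length(unique(nchar(names(mbc_table)))) != 1) {
    stop("mbc_table must be named by barcodes of one common length")
  }
  structure(list(mbc_length = nchar(names(mbc_table)[1]),
                 umi_length = as.integer(umi_length),
                 mbc_table = mbc_table),
            class = "barcode_layout")
}

#' Extract MBC and UMI barcodes from raw reads
#'
#' Splits each read into its MBC, UMI and insert. An MBC absent from the
#' layout's code table is mapped to class `"unknown"` and flagged; reads
#' shorter than MBC + UMI cannot yield an insert and are rejected.
#'
#' @param reads data.frame of raw reads with columns `read_id`, `sequence`,
#'   `quality` (Phred+33 string, same length as `sequence`).
#' @param layout a [barcode_layout()].
#' @return list with `reads` (data.frame: `read_id`, `mbc`, `mbc_class`,
#'   `mbc_known`, `umi`, `sequence`, `quality` — sequence/quality are the
#'   insert only, possibly empty) and `rejected` (data.frame: `read_id`,
#'   `reason`).
#' @export
extract_barcodes <- function(reads, layout) {
  stopifnot(inherits(layout, "barcode_layout"),
            all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("sequence and quality lengths differ")
  }
  bl <- layout$mbc_length + layout$umi_length
  too_short <- nchar(reads$sequence) < bl
  rejected <- data.frame(read_id = reads$read_id[too_short],
                         reason = rep("too_short_for_barcodes", sum(too_short)),
                         stringsAsFactors = FALSE)
  kept <- reads[!too_short, , drop = FALSE]
  mbc <- substr(kept$sequence, 1L, layout$mbc_length)
  cls <- unname(layout$mbc_table[mbc])
  known <- !is.na(cls)
  cls[!known] <- "unknown"
  out <- data.frame(
    read_id = kept$read_id,
    mbc = mbc,
    mbc_class = cls,
    mbc_known = known,
    umi = substr(kept$sequence, layout$mbc_length + 1L, bl),
    sequence = substr(kept$sequence, bl + 1L, nchar(kept$sequence)),
    quality = substr(kept$quality, bl + 1L, nchar(kept$quality)),
    stringsAsFactors = FALSE
  )
  list(reads = out, rejected = rejected)
}

# Phred+33 decode
phred_ints <- function(qual) {
  lapply(qual, function(q) if (nchar(q) == 0) integer() else utf8ToInt(q) - 33L)
}

# 3' running-window quality trim: scanning 5'->3' with a window of
# `window` bases, the read is cut before the first window whose mean
# quality drops below min_quality.
trim_length <- function(q, min_quality, window = 4L) {
  n <- length(q)
  if (n == 0) return(0L)
  if (n < window) {
    return(if (mean(q) >= min_quality) n else 0L)
  }
  cm <- cumsum(c(0L, q))
  wmean <- (cm[(window + 1L):(n + 1L)] - cm[1:(n - window + 1L)]) / window
  bad <- which(wmean < min_quality)
  if (length(bad) == 0) n else bad[1] - 1L
}

#' Length- and quality-filter barcode-stripped inserts
#'
#' Trims low-quality 3' ends (running window of 4 bases, cut where the
#' window mean drops below `min_quality`) and removes inserts shorter than
#' `min_length` bases after trimming.
#'
#' @param inserts data.frame with `read_id`, `sequence`, `quality`.
#' @param min_length minimum surviving insert length (default 30).
#' @param min_quality Phred threshold for the trimming window (default 20).
#' @return the surviving rows, sequences/qualities trimmed.
#' @export
filter_reads <- function(inserts, min_length = 30L, min_quality = 20L) {
  if (nrow(inserts) == 0) return(inserts)
  qs <- phred_ints(inserts$quality)
  keep_len <- vapply(qs, trim_length, integer(1), min_quality = min_quality)
  out <- inserts
  out$sequence <- substr(out$sequence, 1L, keep_len)
  out$quality <- substr(out$quality, 1L, keep_len)
  out[keep_len >= min_length, , drop = FALSE]
}

#' Deduplicate mapped reads by barcode and mapping position
#'
#' Collapses PCR duplicates: reads sharing (modification class, UMI,
#' contig, strand, 5' start) are one molecule. The retained read is the
#' lexicographically smallest `read_id`, which makes the operation
#' deterministic and idempotent. Reads of different modification classes
#' are never merged.
#'
#' @param reads mapped-read data.frame with columns `mbc_class`, `umi`,
#'   `contig`, `strand`, `pos0`, `read_id` (other columns pass through).
#' @return data.frame with one row per duplicate group, in (contig, pos0,
#'   strand, class, umi) order.
#' @export
deduplicate <- function(reads) {
  need <- c("read_id", "mbc_class", "umi", "contig", "strand", "pos0")
  stopifnot(all(need %in% names(reads)))
  if (nrow(reads) == 0) return(reads)
  o <- order(reads$contig, reads$pos0, reads$strand, reads$mbc_class,
             reads$umi, reads$read_id, method = "radix")
  srt <- reads[o, , drop = FALSE]
  # integer key combination (faster than pasting strings at this scale)
  ku <- match(srt$umi, unique(srt$umi))
  kc <- match(srt$contig, unique(srt$contig))
  km <- match(srt$mbc_class, unique(srt$mbc_class))
  ks <- match(srt$strand, c("+", "-"))
  key <- (((ku - 1) * max(kc) + (kc - 1)) * max(km) + (km - 1)) * 2 + ks
  key <- key * (max(srt$pos0) + 1) + srt$pos0
  out <- srt[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read raw reads from FASTQ
#' @param path FASTQ file path.
#' @return data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own internal metadata columns
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}
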