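#' Build per-base coverage tracks from mapped reads
#'
#' Computes read-depth vectors per (contig, strand, modification class)
#' from deduplicated mapped reads. Depth at position p is the number of
#' reads whose interval covers p.
#'
#' @param reads mapped-read data.frame (columns `contig`, `pos0`, `length`,
#'   `strand`, `mbc_class`, `read_id`).
#' @param contig_lengths named integer vector of contig lengths.
#' @return named list of coverage tracks, keyed `"contig|strand|class"`;
#'   each track is a list with `contig`, `strand`, `mod_class`, `depth`
#'   (integer vector of contig length).
#' @export
build_coverage <- function(reads, contig_lengths) {
  stopifnot(!is.null(names(contig_lengths)))
  if (nrow(reads) > 0) {
    bad <- !(reads$contig %in% names(contig_lengths)) |
      reads$pos0 < 0 |
      reads$pos0 + reads$length > contig_lengths[reads$contig]
    if (any(bad)) {
      stop(sprintf("read %s maps beyond the end of contig %s",
                   reads$read_id[which(bad)[1]], reads$contig[which(bad)[1]]))
    }
  }
  tracks <- list()
  if (nrow(reads) == 0) return(tracks)
  grp <- split(seq_len(nrow(reads)),
               list(contig = reads$contig, strand = reads$strand,
                    class = reads$mbc_class), drop = TRUE, sep = "|")
  for (key in sort(names(grp), method = "radix")) {
    idx <- grp[[key]]
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    clen <- contig_lengths[[parts[1]]]
    cov <- IRanges::coverage(
      IRanges::IRanges(start = reads$pos0[idx] + 1L,
                       width = reads$length[idx]),
      width = clen)
    tracks[[key]] <- list(contig = parts[1], strand = parts[2],
                          mod_class = parts[3],
                          depth = as.integer(cov))
  }
  tracks
}

track_key <- function(contig, strand, mod_class) {
  paste(contig, strand, mod_class, sep = "|")
}

# Zero-depth track to pair with an enrichment track that has no control
# counterpart (the pseudocount keeps the ratio finite).
empty_track <- function(contig, strand, mod_class, length) {
  list(contig = contig, strand = strand, mod_class = mod_class,
       depth = integer(length))
}
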