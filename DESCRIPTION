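Package: editpeaks
Title: Inosine Peak Calling and ADAR1 Isoform Dependency Analysis for
    Modification-Encoded Enrichment Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for modification-encoded enrichment
    sequencing of RNA (bead-enriched libraries carrying modification
    barcodes and unique molecular identifiers, paired with non-enriched
    solution controls). Extracts and deduplicates barcoded reads, calls
    modification peaks from enrichment-versus-control coverage with
    spike-in scaling and hidden-Markov-model confidence scores, calls
    strand-aware A-to-I editing sites inside inosine peaks from pileup
    columns, annotates peaks to gene features (exon, intron, UTRs,
    lncRNA), and classifies per-gene ADAR1 isoform dependency from
    wild-type versus knockout peak scores. Includes a seeded synthetic
    data generator that plants peaks, editing rates, spike-in
    recoveries, and dependency categories so every stage can be tested
    against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
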