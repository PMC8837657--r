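#' The nine read categories, in priority order
#'
#' Reads are assigned to exactly one category by a strict priority cascade:
#' rRNA, tRNA, miRNA, WAGO-repeats, antisense mRNA, intron, intergenic,
#' no match, sense mRNA. "No match" applies only when a read has neither a
#' genome nor a transcript hit (a junction-spanning antisense read is an
#' antisense-mRNA read, not a no-match); "intergenic" applies when a read is
#' genome-mapped but no other label fires.
#'
#' @return Character vector of the nine labels in rank order.
#' @export
read_categories <- function() {
  c("rRNA", "tRNA", "miRNA", "WAGO_repeats", "antisense_mRNA",
    "intron", "intergenic", "no_match", "sense_mRNA")
}

## Reads (indices) with >= frac of their length inside some interval of `gr`.
reads_overlapping <- function(placements, gr, frac) {
  if (length(gr) == 0 || length(placements$genome_hits) == 0) return(integer())
  h <- GenomicRanges::findOverlaps(placements$genome_hits, gr,
                                   ignore.strand = TRUE)
  if (length(h) == 0) return(integer())
  q <- S4Vectors::queryHits(h)
  ow <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(placements$genome_hits)[q],
    GenomicRanges::ranges(gr)[S4Vectors::subjectHits(h)]))
  len <- GenomicRanges::width(placements$genome_hits)[q]
  keep <- ow >= frac * len
  unique(S4Vectors::mcols(placements$genome_hits)$read[q[keep]])
}

#' Classify every read of a library into one of nine categories
#'
#' Interval classes (rRNA, tRNA, miRNA, WAGO-repeats, intron) fire when any
#' genome hit overlaps a class interval by at least `min_overlap_frac` of
#' the read length; sense/antisense mRNA fire on full-length exact
#' transcript hits. Multimapping reads take the best (highest-priority)
#' label over all their hits.
#'
#' @param placements A [place_reads()] result.
#' @param annotations An [annotation_bundle].
#' @param wago_repeats `GRanges` of WAGO-repeat loci: either called loci
#'   (see [call_wago_repeats()]) or the repeat catalog.
#' @param min_overlap_frac Minimum fraction of the read length that must
#'   overlap a class interval (default 0.5).
#' @return A factor of length `n_reads` with levels [read_categories()].
#' @export
classify_reads <- function(placements, annotations, wago_repeats = NULL,
                           min_overlap_frac = 0.5) {
  n <- placements$n_reads
  lab <- rep(NA_character_, n)
  has_genome <- placements$n_genome_hits > 0L
  mapped <- placements$mapped
  lab[!mapped] <- "no_match"
  lab[has_genome] <- "intergenic"
  sense <- placements$n_tx_hits - placements$n_tx_antisense > 0L
  lab[sense] <- "sense_mRNA"
  introns <- intron_ranges(annotations$models)
  lab[reads_overlapping(placements, introns, min_overlap_frac)] <- "intron"
  lab[placements$n_tx_antisense > 0L] <- "antisense_mRNA"
  if (!is.null(wago_repeats))
    lab[reads_overlapping(placements, wago_repeats, min_overlap_frac)] <- "WAGO_repeats"
  lab[reads_overlapping(placements, annotations$miRNA, min_overlap_frac)] <- "miRNA"
  lab[reads_overlapping(placements, annotations$tRNA, min_overlap_frac)] <- "tRNA"
  lab[reads_overlapping(placements, annotations$rRNA, min_overlap_frac)] <- "rRNA"
  factor(lab, levels = read_categories())
}

#' Size and first-nucleotide profile
#'
#' Copy-number-weighted counts of reads by length (18-30 nt window) and
#' first nucleotide, with T reported as U. Out-of-window reads are tallied
#' in the `out_of_range` attribute rather than the matrix.
#'
#' @param lib An [srna_library].
#' @param range Integer lengths to profile (default 18:30).
#' @return A `length x nucleotide` (13 x 4) integer matrix with attributes
#'   `out_of_range` (copies outside the window) and `lib_id`.
#' @export
size_profile <- function(lib, range = 18:30) {
  r <- lib$reads
  inw <- r$length %in% range
  m <- stats::xtabs(count ~ factor(length, levels = range) + first_nt,
                    data = r[inw, , drop = FALSE])
  m <- matrix(as.integer(m), nrow = length(range),
              dimnames = list(length = as.character(range),
                              first_nt = c("A", "C", "G", "U")))
  attr(m, "out_of_range") <- sum(r$count[!inw])
  attr(m, "lib_id") <- lib$id
  m
}

#' Per-category read-count and fraction profile
#'
#' Copy-number-weighted category composition of a library over reads in the
#' 18-30 nt window. Fractions sum to 1 over the nine categories.
#'
#' @param labels Factor from [classify_reads()].
#' @param lib The [srna_library] the labels belong to.
#' @param range Length window (default 18:30).
#' @return A data.frame with columns `category`, `count`, `fraction` and
#'   attribute `lib_id`.
#' @export
category_profile <- function(labels, lib, range = 18:30) {
  r <- lib$reads
  stopifnot(length(labels) == nrow(r))
  inw <- r$length %in% range
  if (!any(inw)) stopf("no classified reads in the %d-%d nt window",
                       min(range), max(range))
  counts <- vapply(split(r$count[inw], labels[inw]), sum, 0)
  out <- data.frame(category = factor(read_categories(), levels = read_categories()),
                    count = as.numeric(counts[read_categories()]),
                    fraction = as.numeric(counts[read_categories()]) / sum(counts))
  attr(out, "lib_id") <- lib$id
  out
}
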