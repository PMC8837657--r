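#' Build an exact-match placement index
#'
#' Prepares a genome (and, when gene models are supplied, the spliced
#' transcriptome) for exact full-length placement of short reads. Contigs
#' and transcripts are concatenated with `N` spacers into single search
#' subjects; matching itself uses Aho-Corasick multi-pattern search
#' (Biostrings `PDict`/`matchPDict`), so an A/C/G/T read can never match
#' across a spacer.
#'
#' @param genome A [genome_index].
#' @param models Optional [gene_models]; enables transcript placement,
#'   including reads spanning exon-exon junctions.
#' @param k Minimum supported read length (placement is full-length exact
#'   matching; `k` below 8 is refused as a degenerate-index guard).
#' @param tx_seqs Optional precomputed [transcript_seqs()] result (avoids
#'   recomputation when the caller already has it).
#' @return An object of class `placement_index`.
#' @export
build_index <- function(genome, models = NULL, k = 18L, tx_seqs = NULL) {
  if (k < 8) stopf("k < 8 refused: index would be degenerate")
  spacer <- strrep("N", 31L)
  ## units = every sequence forward, then every sequence reverse-complemented,
  ## so one Aho-Corasick pass finds both orientations of every read
  cat_subject <- function(seqs, unit_names) {
    rc <- Biostrings::reverseComplement(seqs)
    all_seq <- c(as.character(seqs), as.character(rc))
    lens <- rep(Biostrings::width(seqs), 2L)
    offsets <- cumsum(c(0L, head(lens + 31L, -1L)))
    subj <- Biostrings::DNAString(paste(all_seq, collapse = spacer))
    list(subject = subj, offset = offsets, length = lens,
         unit = rep(unit_names, 2L),
         revcomp = rep(c(FALSE, TRUE), each = length(seqs)))
  }
  g <- cat_subject(genome$seqs, names(genome$lengths))
  tx <- NULL
  if (!is.null(models) && length(models$gene_id)) {
    if (is.null(tx_seqs)) tx_seqs <- transcript_seqs(models, genome)
    tx <- cat_subject(tx_seqs, models$gene_id)
  }
  structure(list(genome = genome, models = models, k = as.integer(k),
                 g = g, contigs = names(genome$lengths), tx = tx),
            class = "placement_index")
}

## Match a width-homogeneous PDict against a concatenated two-orientation
## subject. Returns, per hit: pattern index, unit name, start within the
## original (forward) sequence, and whether the hit was on the reverse
## complement. w is the pattern width.
match_concat <- function(pd, w, sub) {
  m <- Biostrings::matchPDict(pd, sub$subject)
  n <- S4Vectors::elementNROWS(m)
  if (sum(n) == 0) {
    return(data.frame(pattern = integer(), unit = character(),
                      start = integer(), revcomp = logical()))
  }
  ir <- unlist(m)
  pattern <- rep(seq_len(length(n)), n)
  wp <- rep_len(w, length(n))[pattern]
  p <- IRanges::start(ir)
  u <- findInterval(p, sub$offset + 1L)
  pos <- p - sub$offset[u]
  L <- sub$length[u]
  rc <- sub$revcomp[u]
  data.frame(pattern = pattern, unit = sub$unit[u],
             start = ifelse(rc, L - pos - wp + 2L, pos),
             revcomp = rc)
}

#' Place a library's reads on genome and transcriptome
#'
#' Finds every exact full-length match of every distinct read, on both
#' genome strands and (if the index carries gene models) against spliced
#' transcript sequences in sense and antisense orientation. A read whose
#' reverse complement matches the top strand is recorded as a minus-strand
#' genome hit. Junction-spanning reads have transcript hits only. Total
#' mapped reads counts the copies of every read with at least one genome or
#' transcript hit.
#'
#' @param lib An [srna_library].
#' @param index A [build_index()] result.
#' @return An object of class `placements`: `genome_hits` (`GRanges` with a
#'   `read` index column), `tx_hits` (data.frame `read`, `gene`, `start`,
#'   `end` in mature-transcript coordinates, `antisense`), per-read hit
#'   counts, and `total_mapped`.
#' @export
place_reads <- function(lib, index) {
  reads <- lib$reads
  nreads <- nrow(reads)
  gh <- vector("list", 0); th <- vector("list", 0)
  if (nreads) {
    widths <- nchar(reads$seq)
    ## one trusted-band dictionary per batch of reads sharing enough length:
    ## the band covers the shortest read; longer reads are verified outside
    ## the band by matchPDict itself
    batches <- split(seq_len(nreads), widths >= index$k)
    for (b in batches) {
      wmin <- min(widths[b])
      if (wmin < 8) {
        b_short <- b[widths[b] < 8]
        warnf("%d read(s) shorter than 8 nt left unplaced", length(b_short))
        b <- b[widths[b] >= 8]
        if (!length(b)) next
        wmin <- min(widths[b])
      }
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads$seq[b]),
                              tb.start = 1L, tb.end = wmin)
      w <- widths[b]
      hit <- match_concat(pd, w, index$g)
      if (nrow(hit)) {
        gh[[length(gh) + 1L]] <- data.frame(
          read = b[hit$pattern], contig = hit$unit,
          start = hit$start, end = hit$start + w[hit$pattern] - 1L,
          strand = ifelse(hit$revcomp, "-", "+"))
      }
      if (!is.null(index$tx)) {
        t <- match_concat(pd, w, index$tx)
        if (nrow(t)) {
          th[[length(th) + 1L]] <- data.frame(
            read = b[t$pattern], gene = t$unit,
            start = t$start, end = t$start + w[t$pattern] - 1L,
            antisense = t$revcomp)
        }
      }
    }
  }
  ghd <- if (length(gh)) do.call(rbind, gh) else
    data.frame(read = integer(), contig = character(), start = integer(),
               end = integer(), strand = character())
  thd <- if (length(th)) do.call(rbind, th) else
    data.frame(read = integer(), gene = character(), start = integer(),
               end = integer(), antisense = logical())
  genome_hits <- GenomicRanges::GRanges(
    seqnames = factor(ghd$contig, levels = index$contigs),
    ranges = IRanges::IRanges(ghd$start, ghd$end),
    strand = ghd$strand, read = ghd$read,
    seqinfo = genome_seqinfo(index$genome))
  n_genome <- tabulate(ghd$read, nbins = nreads)
  n_tx <- tabulate(thd$read, nbins = nreads)
  n_tx_anti <- tabulate(thd$read[thd$antisense], nbins = nreads)
  mapped <- n_genome > 0L | n_tx > 0L
  structure(
    list(lib_id = lib$id, n_reads = nreads, counts = reads$count,
         genome_hits = genome_hits, tx_hits = thd,
         n_genome_hits = n_genome, n_tx_hits = n_tx,
         n_tx_antisense = n_tx_anti, mapped = mapped,
         total_mapped = sum(as.numeric(reads$count[mapped]))),
    class = "placements")
}

#' @export
print.placements <- function(x, ...) {
  cat(sprintf(
    "placements '%s': %d reads, %d genome hits, %d transcript hits, %s copies mapped\n",
    x$lib_id, x$n_reads, length(x$genome_hits), nrow(x$tx_hits),
    format(x$total_mapped, big.mark = ",")))
  invisible(x)
}

#' Normalized weighted coverage track
#'
#' Each read contributes `count / n_genome_hits` to every base of each of
#' its genome hits (fractional multimapper weighting, strand-combined), and
#' the whole track is scaled by `norm_target / total_mapped` so every
#' library is expressed on a common footing of `norm_target` mapped reads.
#'
#' @param placements A [place_reads()] result.
#' @param genome A [genome_index].
#' @param norm_target Normalization target N0 in reads (default 30 million,
#'   the published setting; synthetic runs scale it with genome size).
#' @return An object of class `coverage_track`: `cov` (an `RleList` over
#'   contigs), `norm_factor`, `norm_target`, `total_mapped`, `lib_id`.
#' @export
coverage_track <- function(placements, genome, norm_target = 3e7) {
  if (placements$total_mapped == 0) stopf("library has no mapped reads")
  gr <- placements$genome_hits
  rd <- S4Vectors::mcols(gr)$read
  w <- placements$counts[rd] / placements$n_genome_hits[rd]
  cov <- GenomicRanges::coverage(gr, weight = w)
  f <- norm_target / placements$total_mapped
  structure(list(cov = cov * f, norm_factor = f, norm_target = norm_target,
                 total_mapped = placements$total_mapped,
                 lib_id = placements$lib_id),
            class = "coverage_track")
}

#' Mean normalized genome coverage
#'
#' Total coverage mass divided by total contig length, mitochondrial
#' contigs excluded. This is the baseline against which seed windows
#' (20-fold) and locus enrichment (10-fold) are assessed.
#'
#' @param track A [coverage_track].
#' @param genome A [genome_index].
#' @return A single number.
#' @export
mean_genome_coverage <- function(track, genome) {
  keep <- setdiff(names(genome$lengths), genome$mito_contigs)
  tot <- sum(vapply(keep, function(ch) sum(track$cov[[ch]]), 0))
  tot / sum(as.numeric(genome$lengths[keep]))
}

#' Export a coverage track as bedGraph
#' @param track A [coverage_track].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$cov)) {
    r <- track$cov[[ch]]
    v <- S4Vectors::runValue(r)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, head(ends, -1L))
    keep <- v != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts[keep], ends[keep], v[keep]), con)
  }
  invisible(path)
}
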