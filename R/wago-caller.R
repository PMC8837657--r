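#' Locus-calling parameters
#'
#' The published procedure: coverage normalized to `norm_target` reads;
#' seed windows where coverage is at least `seed_fold` times the genome
#' mean (20-fold over a ~2.5x mean gives the 50x absolute cutoff); seeds
#' within `merge_dist` bp merged; merged loci shorter than `min_length`
#' dropped; loci kept when at least one library shows `enrich_fold`
#' enrichment; loci touching rRNA/tRNA/miRNA/mitochondrial annotation
#' removed.
#'
#' @param norm_target Normalization target N0, reads (default 30e6).
#' @param seed_fold Seed threshold, fold over mean coverage (default 20).
#' @param merge_dist Merge distance D in bp (default 2000).
#' @param min_length Minimum locus length in bp (default 50).
#' @param enrich_fold Enrichment threshold, fold over mean (default 10).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(norm_target = 3e7, seed_fold = 20, merge_dist = 2000,
                          min_length = 50, enrich_fold = 10) {
  stopifnot(norm_target > 0, seed_fold > 0, merge_dist >= 0,
            min_length > 0, enrich_fold > 0)
  structure(list(norm_target = norm_target, seed_fold = seed_fold,
                 merge_dist = merge_dist, min_length = min_length,
                 enrich_fold = enrich_fold),
            class = "caller_params")
}

#' Seed windows: maximal runs of high coverage
#'
#' Returns the maximal runs of consecutive bases whose normalized coverage
#' is at least `seed_fold * mean` (e.g. 20 x 2.5 = an absolute cutoff of
#' 50).
#'
#' @param track A [coverage_track].
#' @param mean_cov Genome mean coverage (see [mean_genome_coverage()]).
#' @param seed_fold Fold threshold over the mean.
#' @return An unstranded `GRanges`.
#' @export
seed_windows <- function(track, mean_cov, seed_fold = 20) {
  if (mean_cov <= 0) stopf("mean coverage is zero; cannot seed")
  cutoff <- seed_fold * mean_cov
  grl <- lapply(names(track$cov), function(ch) {
    ir <- IRanges::ranges(IRanges::slice(track$cov[[ch]], lower = cutoff,
                                         rangesOnly = FALSE))
    if (length(ir) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(seqnames = ch, ranges = ir)
  })
  out <- suppressWarnings(do.call(c, grl))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Merge intervals within a distance
#'
#' Merges intervals on the same contig whenever the gap between them is at
#' most `dist` bp, taking the transitive closure (bedtools `mergeBed -d`
#' semantics). Adjacent and overlapping intervals always merge; merging
#' never crosses contigs. Strand is ignored and dropped.
#'
#' @param gr A `GRanges`.
#' @param dist Maximum gap in bp (default 2000).
#' @return A sorted, unstranded `GRanges`.
#' @export
merge_within <- function(gr, dist = 2000) {
  if (length(gr) == 0) return(GenomicRanges::granges(gr))
  gr <- GenomicRanges::sort(GenomicRanges::granges(gr), ignore.strand = TRUE)
  GenomicRanges::strand(gr) <- "*"
  chr <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  ## sweep: a new run starts when the gap to the furthest end so far > dist
  run_max_end <- cummax_by_group(en, chr)
  prev_max <- c(-Inf, head(run_max_end, -1))
  new_chr <- c(TRUE, chr[-1] != chr[-length(chr)])
  new_run <- new_chr | (st - prev_max - 1 > dist)
  grp <- cumsum(new_run)
  out_st <- tapply(st, grp, min)
  out_en <- tapply(en, grp, max)
  out_chr <- chr[!duplicated(grp)]
  gr2 <- GenomicRanges::GRanges(
    seqnames = out_chr,
    ranges = IRanges::IRanges(as.integer(out_st), as.integer(out_en)))
  GenomeInfoDb::seqlevels(gr2) <- GenomeInfoDb::seqlevels(gr)
  GenomeInfoDb::seqinfo(gr2) <- GenomeInfoDb::seqinfo(gr)
  GenomicRanges::sort(gr2, ignore.strand = TRUE)
}

## cummax of x restarting at each change of group label (groups contiguous)
cummax_by_group <- function(x, group) {
  out <- x
  for (i in seq_along(x)[-1]) {
    if (group[i] == group[i - 1] && out[i - 1] > out[i]) out[i] <- out[i - 1]
  }
  out
}

#' Fold enrichment of loci in a coverage track
#'
#' Mean normalized coverage within each locus divided by the genome mean.
#'
#' @param loci A `GRanges`.
#' @param track A [coverage_track].
#' @param mean_cov Genome mean coverage of the same track.
#' @return Numeric vector, one fold value per locus.
#' @export
enrichment_fold <- function(loci, track, mean_cov) {
  if (any(GenomicRanges::width(loci) == 0)) stopf("zero-length locus")
  if (length(loci) == 0) return(numeric())
  means <- rep(0, length(loci))
  for (ch in unique(as.character(GenomicRanges::seqnames(loci)))) {
    sel <- as.character(GenomicRanges::seqnames(loci)) == ch
    if (!ch %in% names(track$cov)) next
    v <- IRanges::Views(track$cov[[ch]],
                        IRanges::IRanges(GenomicRanges::start(loci)[sel],
                                         GenomicRanges::end(loci)[sel]))
    means[sel] <- IRanges::viewMeans(v)
  }
  means / mean_cov
}

#' rpkm of loci in a library
#'
#' Weighted reads overlapping each locus (count / number of genome hits per
#' read, so a multimapper contributes total mass 1) per kilobase of locus
#' per million mapped reads.
#'
#' @param loci A `GRanges`.
#' @param placements A [place_reads()] result.
#' @return Numeric vector of rpkm values.
#' @export
locus_rpkm <- function(loci, placements) {
  if (any(GenomicRanges::width(loci) == 0)) stopf("zero-length locus")
  if (length(loci) == 0) return(numeric())
  rpkm <- rep(0, length(loci))
  h <- GenomicRanges::findOverlaps(placements$genome_hits, loci,
                                   ignore.strand = TRUE)
  if (length(h)) {
    rd <- S4Vectors::mcols(placements$genome_hits)$read[S4Vectors::queryHits(h)]
    w <- placements$counts[rd] / placements$n_genome_hits[rd]
    mass <- tapply(w, S4Vectors::subjectHits(h), sum)
    rpkm[as.integer(names(mass))] <- as.numeric(mass)
  }
  rpkm / (GenomicRanges::width(loci) / 1e3 * placements$total_mapped / 1e6)
}

#' Call WAGO-repeat loci from WAGO-class coverage tracks
#'
#' The full published procedure: per-library seed windows (at least
#' `seed_fold` x mean coverage) are pooled over all libraries, merged
#' within `merge_dist` bp, filtered to `min_length` bp, kept when at least
#' one library is `enrich_fold`-fold enriched over its genome mean, and
#' finally purged of loci overlapping (by 1 bp or more) rRNA, tRNA or
#' miRNA annotation or lying on a mitochondrial contig.
#'
#' @param tracks List of [coverage_track]s, one per WAGO-class library.
#' @param annotations An [annotation_bundle] (for the blacklist).
#' @param genome A [genome_index].
#' @param params A [caller_params].
#' @param placements Optional list of [place_reads()] results parallel to
#'   `tracks`; when given, a per-library rpkm matrix is attached.
#' @return A `GRanges` of loci with metadata `name` (locus id), `max_fold`
#'   and `score` (max fold x 10, capped at 1000); attributes `rpkm`
#'   (loci x libraries matrix, if `placements` given), `fold` (loci x
#'   libraries fold matrix) and `blacklisted` (the loci removed by the
#'   annotation filter).
#' @export
call_wago_repeats <- function(tracks, annotations, genome,
                              params = caller_params(), placements = NULL) {
  if (length(tracks) == 0) stopf("no libraries supplied")
  lib_ids <- vapply(tracks, function(t) t$lib_id, "")
  means <- vapply(tracks, mean_genome_coverage, 0, genome = genome)
  if (any(means <= 0)) stopf("genome mean coverage is zero for library %s",
                             lib_ids[means <= 0][1])
  seeds <- lapply(seq_along(tracks), function(i)
    seed_windows(tracks[[i]], means[i], params$seed_fold))
  pooled <- suppressWarnings(do.call(c, seeds))
  loci <- merge_within(pooled, params$merge_dist)
  loci <- loci[GenomicRanges::width(loci) >= params$min_length]
  fold <- vapply(seq_along(tracks), function(i)
    enrichment_fold(loci, tracks[[i]], means[i]),
    numeric(length(loci)))
  fold <- matrix(fold, nrow = length(loci), dimnames = list(NULL, lib_ids))
  max_fold <- if (length(loci)) apply(fold, 1, max) else numeric()
  keep <- max_fold >= params$enrich_fold
  loci <- loci[keep]; fold <- fold[keep, , drop = FALSE]
  max_fold <- max_fold[keep]
  bl <- blacklist_ranges(annotations, genome)
  hit_bl <- IRanges::overlapsAny(loci, bl, ignore.strand = TRUE)
  blacklisted <- loci[hit_bl]
  loci <- loci[!hit_bl]; fold <- fold[!hit_bl, , drop = FALSE]
  max_fold <- max_fold[!hit_bl]
  S4Vectors::mcols(loci)$name <- sprintf("wago_repeat_%04d", seq_along(loci))
  S4Vectors::mcols(loci)$max_fold <- max_fold
  S4Vectors::mcols(loci)$score <- pmin(round(max_fold * 10), 1000)
  if (!is.null(placements)) {
    rpkm <- vapply(placements, function(p) locus_rpkm(loci, p),
                   numeric(length(loci)))
    rpkm <- matrix(rpkm, nrow = length(loci),
                   dimnames = list(S4Vectors::mcols(loci)$name, lib_ids))
    attr(loci, "rpkm") <- rpkm
  }
  attr(loci, "fold") <- matrix(fold, nrow = length(loci),
                               dimnames = list(S4Vectors::mcols(loci)$name, lib_ids))
  attr(loci, "blacklisted") <- blacklisted
  loci
}

#' Overlap fraction between two locus sets
#'
#' Fraction of the query set's base pairs covered by the subject set, plus
#' the intersected intervals. This is the statistic behind statements such
#' as "~77% of NRDE-3 target sequence overlaps WAGO-1/2 targets".
#'
#' @param query,subject `GRanges`.
#' @return A list with `fraction` (intersected bp / query bp) and
#'   `intersection` (a `GRanges`).
#' @export
target_overlap <- function(query, subject) {
  q <- GenomicRanges::reduce(GenomicRanges::granges(query), ignore.strand = TRUE)
  s <- GenomicRanges::reduce(GenomicRanges::granges(subject), ignore.strand = TRUE)
  GenomicRanges::strand(q) <- "*"; GenomicRanges::strand(s) <- "*"
  inter <- suppressWarnings(GenomicRanges::intersect(q, s, ignore.strand = TRUE))
  qbp <- sum(as.numeric(GenomicRanges::width(q)))
  list(fraction = if (qbp > 0) sum(as.numeric(GenomicRanges::width(inter))) / qbp
       else 0,
       intersection = inter)
}
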