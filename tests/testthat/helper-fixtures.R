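## Shared fixtures, built in code. The tiny genome has one gene with two
## exons on each strand, one rRNA, one miRNA and one repeat locus, so every
## classifier category is reachable by construction.

tiny_genome <- function(seed = 404) {
  wagoseq:::local_seed(seed, {
    chr1 <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
    mito <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                  collapse = "")
    genome_index(Biostrings::DNAStringSet(c(chr1 = chr1, mito = mito)),
                 mito_contigs = "mito")
  })
}

tiny_models <- function(genome) {
  exl <- GenomicRanges::GRangesList(
    gplus = GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(c(1001, 1501), c(1200, 1700)), strand = "+"),
    gminus = GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(c(3001, 3401), c(3200, 3600)), strand = "-"))
  gene_models(exl, genome)
}

tiny_annotations <- function(genome, models) {
  annotation_bundle(
    genome, models,
    rRNA = GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5500),
                                  strand = "+"),
    tRNA = GenomicRanges::GRanges("chr1", IRanges::IRanges(6001, 6080),
                                  strand = "+"),
    miRNA = GenomicRanges::GRanges("chr1", IRanges::IRanges(7001, 7022),
                                   strand = "+"),
    repeats = GenomicRanges::GRanges("chr1", IRanges::IRanges(8001, 8800),
                                     strand = "+"))
}

## substring of a contig / its reverse complement, as a read sequence
gseq <- function(genome, chr, start, end, rc = FALSE) {
  s <- substring(as.character(genome$seqs[[chr]]), start, end)
  if (rc) wagoseq:::revcomp(s) else s
}

## a default-scale simulated genome, generated once per test run
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_genome(sim_config(seed = 11))
    cache
  }
})

shared_index <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- shared_sim()
      cache <<- build_index(sim$genome, sim$models,
                            tx_seqs = Biostrings::DNAStringSet(sim$tx_strings))
    }
    cache
  }
})

## hand-built placements object for arithmetic tests
fake_placements <- function(counts, genome_hits = NULL, tx_hits = NULL,
                            total_mapped = sum(counts), lib_id = "fake") {
  n <- length(counts)
  if (is.null(genome_hits))
    genome_hits <- GenomicRanges::GRanges()
  if (is.null(tx_hits))
    tx_hits <- data.frame(read = integer(), gene = character(),
                          start = integer(), end = integer(),
                          antisense = logical())
  rd <- if (length(genome_hits)) S4Vectors::mcols(genome_hits)$read else integer()
  n_genome <- tabulate(rd, nbins = n)
  n_tx <- tabulate(tx_hits$read, nbins = n)
  n_anti <- tabulate(tx_hits$read[tx_hits$antisense], nbins = n)
  structure(list(lib_id = lib_id, n_reads = n, counts = counts,
                 genome_hits = genome_hits, tx_hits = tx_hits,
                 n_genome_hits = n_genome, n_tx_hits = n_tx,
                 n_tx_antisense = n_anti,
                 mapped = n_genome > 0L | n_tx > 0L,
                 total_mapped = total_mapped),
            class = "placements")
}

## hand-built coverage track from per-contig numeric vectors
fake_track <- function(vectors, lib_id = "fake", norm_target = 1,
                       total_mapped = 1) {
  structure(list(cov = IRanges::RleList(lapply(vectors, S4Vectors::Rle),
                                        compress = FALSE),
                 norm_factor = 1, norm_target = norm_target,
                 total_mapped = total_mapped, lib_id = lib_id),
            class = "coverage_track")
}

## reciprocal >= 50% overlap matching of called loci against truth loci
recip_match <- function(called, truth) {
  h <- GenomicRanges::findOverlaps(called, truth, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
  ow <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(called)[q], GenomicRanges::ranges(truth)[s]))
  ok <- ow >= 0.5 * GenomicRanges::width(called)[q] &
    ow >= 0.5 * GenomicRanges::width(truth)[s]
  list(precision = if (length(called)) length(unique(q[ok])) / length(called) else NA,
       recall = if (length(truth)) length(unique(s[ok])) / length(truth) else NA)
}

## independent transitive-closure merge oracle: boolean adjacency matrix
## (gap <= dist, same contig), closed by repeated boolean matrix products
merge_oracle <- function(gr, dist) {
  chr <- as.character(GenomicRanges::seqnames(gr))
  out <- list()
  for (ch in sort(unique(chr))) {
    st <- GenomicRanges::start(gr)[chr == ch]
    en <- GenomicRanges::end(gr)[chr == ch]
    n <- length(st)
    A <- outer(st, en + dist + 1, "<=") & t(outer(st, en + dist + 1, "<="))
    repeat {
      A2 <- (A %*% A) > 0
      if (identical(A2, A)) break
      A <- A2
    }
    comp <- apply(A, 1, function(r) min(which(r)))
    out[[ch]] <- data.frame(
      chr = ch,
      start = as.integer(tapply(st, comp, min)),
      end = as.integer(tapply(en, comp, max)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chr, df$start), , drop = FALSE]
  GenomicRanges::GRanges(df$chr, IRanges::IRanges(df$start, df$end))
}

## order-independent canonical form of an unstranded GRanges
gr_frame <- function(gr) {
  df <- data.frame(chr = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr))
  df <- df[order(df$chr, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}
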