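test_that("exact placement finds planted substrings on both strands", {
  g <- tiny_genome()
  idx <- build_index(g)
  expect_error(build_index(g, k = 4), "k < 8")

  fwd <- gseq(g, "chr1", 2001, 2022)            # sense 22-mer
  rev <- gseq(g, "chr1", 4001, 4022, rc = TRUE) # antisense 22-mer
  absent <- strrep("A", 22)                     # essentially never present
  lib <- srna_library(c(fwd, rev, absent), c(1L, 1L, 1L))
  pl <- place_reads(lib, idx)
  i_fwd <- which(lib$reads$seq == fwd)
  i_rev <- which(lib$reads$seq == rev)
  i_abs <- which(lib$reads$seq == absent)
  gh <- pl$genome_hits
  rd <- S4Vectors::mcols(gh)$read
  expect_equal(GenomicRanges::start(gh[rd == i_fwd]), 2001L)
  expect_equal(as.character(GenomicRanges::strand(gh[rd == i_fwd])), "+")
  expect_equal(GenomicRanges::start(gh[rd == i_rev]), 4001L)
  expect_equal(as.character(GenomicRanges::strand(gh[rd == i_rev])), "-")
  expect_equal(pl$n_genome_hits[i_abs], 0L)
  expect_equal(pl$total_mapped, 2)
})

test_that("multi-copy substrings yield one hit per occurrence", {
  g0 <- tiny_genome()
  read <- gseq(g0, "chr1", 501, 520)  # 20-mer, then planted a second time
  seqs <- as.character(g0$seqs)
  seqs[["chr1"]] <- paste0(seqs[["chr1"]], read, strrep("T", 10))
  g <- genome_index(Biostrings::DNAStringSet(seqs))
  idx <- build_index(g)
  pl <- place_reads(srna_library(read), idx)
  expect_equal(pl$n_genome_hits[1], 2L)
  expect_setequal(GenomicRanges::start(pl$genome_hits), c(501L, 10001L))
})

test_that("junction-spanning antisense reads hit transcripts only", {
  g <- tiny_genome()
  m <- tiny_models(g)
  idx <- build_index(g, m)
  tx <- as.character(transcript_seqs(m, g)[["gplus"]])
  ## 22-mer centered on the exon1/exon2 junction (position 200|201)
  jread <- wagoseq:::revcomp(substring(tx, 190, 211))
  lib <- srna_library(jread)
  pl <- place_reads(lib, idx)
  expect_equal(pl$n_genome_hits[1], 0L)
  expect_equal(pl$n_tx_hits[1], 1L)
  expect_true(pl$tx_hits$antisense[1])
  expect_equal(pl$tx_hits$start[1], 190L)
  expect_equal(pl$total_mapped, 1)

  ## an exonic antisense read hits both genome and transcript, consistently
  eread <- gseq(g, "chr1", 1051, 1072, rc = TRUE)
  pl2 <- place_reads(srna_library(eread), idx)
  expect_equal(pl2$n_genome_hits[1], 1L)
  expect_equal(as.character(GenomicRanges::strand(pl2$genome_hits)), "-")
  expect_equal(pl2$tx_hits$antisense[1], TRUE)
  expect_equal(pl2$tx_hits$start[1], 51L)  # offset on the mature transcript
})

test_that("placement equals a naive substring scan on a small genome", {
  ## oracle: gregexpr on the contig strings and their reverse complements.
  ## c2 carries an exact copy of part of c1, so multimapping hits occur.
  set.seed(91)
  c1 <- paste(sample(c("A", "C", "G", "T"), 32000, replace = TRUE),
              collapse = "")
  c2 <- paste0(paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE),
                     collapse = ""),
               substring(c1, 5001, 9000),
               wagoseq:::revcomp(substring(c1, 12001, 14000)))
  genome <- genome_index(Biostrings::DNAStringSet(c(c1 = c1, c2 = c2)))
  idx <- build_index(genome)
  contigs <- as.character(genome$seqs)
  ## reads: half sampled from the genome (guaranteed hits, incl. repeats),
  ## half random (mostly no hits)
  n <- 1000
  lens <- sample(18:30, n, replace = TRUE)
  seqs <- character(n)
  for (i in seq_len(n)) {
    if (i %% 2 == 0) {
      ch <- sample(names(contigs), 1)
      st <- sample.int(nchar(contigs[[ch]]) - lens[i], 1)
      s <- substring(contigs[[ch]], st, st + lens[i] - 1L)
      if (runif(1) < 0.5) s <- wagoseq:::revcomp(s)
      seqs[i] <- s
    } else {
      seqs[i] <- paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE),
                       collapse = "")
    }
  }
  lib <- srna_library(seqs)
  pl <- place_reads(lib, idx)
  gh <- data.frame(read = S4Vectors::mcols(pl$genome_hits)$read,
                   chr = as.character(GenomicRanges::seqnames(pl$genome_hits)),
                   start = GenomicRanges::start(pl$genome_hits),
                   strand = as.character(GenomicRanges::strand(pl$genome_hits)))
  scan_hits <- function(s) {
    out <- list()
    for (ch in names(contigs)) {
      p <- gregexpr(s, contigs[[ch]], fixed = TRUE)[[1]]
      if (p[1] != -1) out[[length(out) + 1]] <-
          data.frame(chr = ch, start = as.integer(p), strand = "+")
      prc <- gregexpr(wagoseq:::revcomp(s), contigs[[ch]], fixed = TRUE)[[1]]
      if (prc[1] != -1) out[[length(out) + 1]] <-
          data.frame(chr = ch, start = as.integer(prc), strand = "-")
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(chr = character(), start = integer(), strand = character())
  }
  for (i in seq_len(nrow(lib$reads))) {
    got <- gh[gh$read == i, c("chr", "start", "strand")]
    want <- scan_hits(lib$reads$seq[i])
    got <- got[order(got$chr, got$start, got$strand), ]
    want <- want[order(want$chr, want$start, want$strand), ]
    expect_equal(unname(as.list(got)), unname(as.list(want)),
                 label = paste("read", i))
  }
})

test_that("coverage uses fractional multimapper weights and N0 scaling", {
  g <- genome_index(Biostrings::DNAStringSet(
    c(cA = strrep("A", 100), cB = strrep("C", 100))))
  gh <- GenomicRanges::GRanges(
    c("cA", "cA"), IRanges::IRanges(c(11, 51), width = 20), strand = "+",
    read = c(1L, 1L), seqinfo = genome_seqinfo(g))
  pl <- fake_placements(counts = 10L, genome_hits = gh, total_mapped = 15)
  tr <- coverage_track(pl, g, norm_target = 30)
  ## each of the 2 hits gets 10/2 = 5 before scaling; N0/total = 2 after
  expect_equal(unique(S4Vectors::runValue(tr$cov[["cA"]])), c(0, 10))
  expect_equal(tr$norm_factor, 2)
  ## mass conservation: sum(track) = count x length x factor
  expect_equal(sum(sum(tr$cov)), 10 * 20 * 2)
})

test_that("mean genome coverage averages over non-mito contigs", {
  g <- genome_index(Biostrings::DNAStringSet(
    c(cA = strrep("A", 100), cB = strrep("C", 100), mt = strrep("G", 50))),
    mito_contigs = "mt")
  tr <- fake_track(list(cA = rep(1, 100), cB = rep(3, 100), mt = rep(99, 50)))
  expect_equal(mean_genome_coverage(tr, g), 2)
  tr0 <- fake_track(list(cA = rep(0, 100), cB = rep(0, 100), mt = rep(0, 50)))
  expect_equal(mean_genome_coverage(tr0, g), 0)
})

test_that("doubling every count leaves the normalized track identical", {
  sim <- shared_sim()
  idx <- shared_index()
  sl <- simulate_library(sim, "WAGO12_like", "M2", depth = 20000, seed = 77)
  pl1 <- place_reads(sl$library, idx)
  lib2 <- sl$library
  lib2$reads$count <- lib2$reads$count * 2L
  pl2 <- place_reads(lib2, idx)
  t1 <- coverage_track(pl1, sim$genome, norm_target = 20000)
  t2 <- coverage_track(pl2, sim$genome, norm_target = 20000)
  for (ch in names(t1$cov)) {
    expect_lt(max(abs(as.numeric(t1$cov[[ch]]) - as.numeric(t2$cov[[ch]]))),
              1e-9)
  }
})
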