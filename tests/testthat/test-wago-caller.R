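test_that("seed windows apply the absolute cutoff implied by fold x mean", {
  ## 20-fold over a 2.5x mean is an absolute cutoff of 50x
  v <- rep(0, 1000); v[301:400] <- 60
  tr <- fake_track(list(chr1 = v))
  seeds <- seed_windows(tr, mean_cov = 2.5, seed_fold = 20)
  expect_equal(length(seeds), 1L)
  expect_equal(GenomicRanges::start(seeds), 301L)
  expect_equal(GenomicRanges::width(seeds), 100L)

  ## brute-force per-base threshold scan agrees
  hot <- which(v >= 20 * 2.5)
  expect_equal(hot, 301:400)

  ## a uniform track at the mean yields no seeds
  tru <- fake_track(list(chr1 = rep(2.5, 1000)))
  expect_length(seed_windows(tru, 2.5, 20), 0)
  expect_error(seed_windows(tr, 0, 20), "mean coverage is zero")

  ## values exactly at the cutoff are included (>= semantics)
  v2 <- rep(0, 100); v2[11:20] <- 50
  expect_equal(GenomicRanges::width(
    seed_windows(fake_track(list(c = v2)), 2.5, 20)), 10L)
})

test_that("merge_within follows mergeBed -d gap semantics", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 1501), c(200, 1600)))
  m <- merge_within(gr, 2000)   # gap 1300 <= 2000 -> merge
  expect_equal(length(m), 1L)
  expect_equal(GenomicRanges::start(m), 101L)
  expect_equal(GenomicRanges::end(m), 1600L)

  gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 2701), c(200, 2800)))
  expect_length(merge_within(gr2, 2000), 2L)  # gap 2500 -> unmerged
  ## boundary: gap exactly dist merges, dist + 1 does not
  gr3 <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 2102), c(100, 2200)))
  expect_length(merge_within(gr3, 2001), 1L)
  expect_length(merge_within(gr3, 2000), 2L)

  single <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 10))
  expect_equal(GenomicRanges::ranges(merge_within(single, 2000)),
               GenomicRanges::ranges(single))

  ## merging never crosses contigs
  gr4 <- GenomicRanges::GRanges(c("a", "b"), IRanges::IRanges(c(1, 5), c(10, 20)))
  expect_length(merge_within(gr4, 1e6), 2L)
})

test_that("merge_within equals the transitive-closure oracle on random sets", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(1:60, 1)
    gr <- GenomicRanges::GRanges(
      sample(c("c1", "c2"), n, replace = TRUE),
      IRanges::IRanges(start = sample.int(20000, n, replace = TRUE),
                       width = sample.int(500, n, replace = TRUE)))
    d <- sample(c(0L, 10L, 100L, 2000L), 1)
    got <- merge_within(gr, d)
    want <- merge_oracle(gr, d)
    expect_equal(gr_frame(got), gr_frame(want))
    ## cross-check against the interval-package reduction
    red <- GenomicRanges::reduce(got, min.gapwidth = d + 1L)
    expect_equal(length(red), length(got))
  }
})

test_that("enrichment fold and locus rpkm match hand arithmetic", {
  v <- rep(0, 1000); v[101:200] <- 60
  tr <- fake_track(list(chr1 = v))
  loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  expect_equal(enrichment_fold(loci, tr, 2.4), 25)

  ## 250 weighted reads in a 500 bp locus, 30 M mapped -> 16.667 rpkm
  g <- genome_index(Biostrings::DNAStringSet(c(chr1 = strrep("A", 2000))))
  gh <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(rep(300, 250), width = 20),
                               strand = "+", read = 1:250,
                               seqinfo = genome_seqinfo(g))
  pl <- fake_placements(counts = rep(1L, 250), genome_hits = gh,
                        total_mapped = 3e7)
  locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 700))
  expect_equal(locus_rpkm(locus, pl), 250 / (0.5 * 30), tolerance = 1e-12)

  ## a read-free locus has rpkm 0 and fold 0
  cold <- GenomicRanges::GRanges("chr1", IRanges::IRanges(801, 900))
  expect_equal(locus_rpkm(cold, pl), 0)
  expect_equal(enrichment_fold(cold, tr, 2.4), 0)
})

test_that("the caller recovers planted loci and applies every filter", {
  sim <- shared_sim()
  idx <- shared_index()
  pls <- list(); tracks <- list()
  for (i in 1:2) {
    sl <- simulate_library(sim, "WAGO12_like", "M2", seed = 1100 + i)
    pls[[i]] <- place_reads(sl$library, idx)
    tracks[[i]] <- coverage_track(pls[[i]], sim$genome,
                                  norm_target = sim$config$norm_target)
  }
  params <- caller_params(norm_target = sim$config$norm_target)
  loci <- suppressWarnings(call_wago_repeats(tracks, sim$annotations,
                                             sim$genome, params,
                                             placements = pls))
  m <- recip_match(loci, sim$truth$planted_repeats)
  expect_gte(m$precision, 0.95)
  expect_gte(m$recall, 0.95)

  ## every locus satisfies the contract
  expect_true(all(GenomicRanges::width(loci) >= params$min_length))
  expect_true(all(S4Vectors::mcols(loci)$max_fold >= params$enrich_fold))
  bl <- blacklist_ranges(sim$annotations, sim$genome)
  expect_false(any(IRanges::overlapsAny(loci, bl, ignore.strand = TRUE)))
  rpkm <- attr(loci, "rpkm")
  expect_equal(dim(rpkm), c(length(loci), 2L))
  expect_true(all(rpkm >= 0))

  ## monotonicity: raising the enrichment fold never adds loci,
  ## raising the length floor never adds loci
  stricter <- suppressWarnings(call_wago_repeats(
    tracks, sim$annotations, sim$genome,
    caller_params(norm_target = sim$config$norm_target, enrich_fold = 25)))
  expect_true(all(IRanges::overlapsAny(stricter, loci)))
  expect_lte(length(stricter), length(loci))
  longer <- suppressWarnings(call_wago_repeats(
    tracks, sim$annotations, sim$genome,
    caller_params(norm_target = sim$config$norm_target, min_length = 500)))
  expect_lte(length(longer), length(loci))

  ## idempotence: coverage restricted to the called loci re-calls them
  masked <- tracks[[1]]
  for (ch in names(masked$cov)) {
    keep <- S4Vectors::Rle(rep(0, length(masked$cov[[ch]])))
    sel <- loci[as.character(GenomicRanges::seqnames(loci)) == ch]
    if (length(sel)) {
      ir <- IRanges::IRanges(GenomicRanges::start(sel), GenomicRanges::end(sel))
      v <- as.numeric(masked$cov[[ch]])
      w <- rep(0, length(v))
      idxs <- unlist(lapply(seq_along(ir), function(j)
        seq.int(IRanges::start(ir)[j], IRanges::end(ir)[j])))
      w[idxs] <- v[idxs]
      keep <- S4Vectors::Rle(w)
    }
    masked$cov[[ch]] <- keep
  }
  recalled <- suppressWarnings(call_wago_repeats(
    list(masked), sim$annotations, sim$genome,
    caller_params(norm_target = sim$config$norm_target)))
  mm <- recip_match(recalled, loci)
  expect_gte(mm$recall, 0.95)

  ## doubling all read counts changes nothing (normalization invariance)
  pls2 <- pls
  for (i in 1:2) {
    pls2[[i]]$counts <- pls2[[i]]$counts * 2L
    pls2[[i]]$total_mapped <- pls2[[i]]$total_mapped * 2
  }
  tracks2 <- lapply(pls2, coverage_track, genome = sim$genome,
                    norm_target = sim$config$norm_target)
  loci2 <- suppressWarnings(call_wago_repeats(tracks2, sim$annotations,
                                              sim$genome, params))
  expect_equal(GenomicRanges::ranges(loci2), GenomicRanges::ranges(loci))
})

test_that("loci overlapping the blacklist are removed but logged", {
  g <- genome_index(Biostrings::DNAStringSet(
    c(chr1 = strrep("A", 10000), mt = strrep("C", 500))), mito_contigs = "mt")
  models <- gene_models(GenomicRanges::GRangesList(), g)
  ann <- annotation_bundle(
    g, models,
    rRNA = GenomicRanges::GRanges("chr1", IRanges::IRanges(2000, 2500)))
  v <- rep(0, 10000)
  v[1001:1100] <- 100    # clean locus
  v[2451:2550] <- 100    # overlaps the rRNA interval by 50 bp
  tr <- fake_track(list(chr1 = v, mt = rep(0, 500)), total_mapped = 1)
  loci <- call_wago_repeats(list(tr), ann, g, caller_params(merge_dist = 100))
  expect_equal(length(loci), 1L)
  expect_equal(GenomicRanges::start(loci), 1001L)
  blk <- attr(loci, "blacklisted")
  expect_equal(length(blk), 1L)
  expect_equal(GenomicRanges::start(blk), 2451L)
})

test_that("target_overlap computes base-pair overlap fractions", {
  a <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 201), c(100, 300)))
  expect_equal(target_overlap(a, a)$fraction, 1)
  b <- GenomicRanges::GRanges("c", IRanges::IRanges(401, 500))
  expect_equal(target_overlap(a, b)$fraction, 0)
  q <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 100))
  s <- GenomicRanges::GRanges("c", IRanges::IRanges(51, 150))
  expect_equal(target_overlap(q, s)$fraction, 0.5)
  expect_equal(GenomicRanges::width(target_overlap(q, s)$intersection), 50L)
})
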