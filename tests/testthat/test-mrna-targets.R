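test_that("antisense gene rpkm matches hand arithmetic", {
  g <- tiny_genome()
  m <- tiny_models(g)   # both genes have mature length 400
  ## 12 antisense reads on gplus, 1 M mapped -> 12 / (0.4 * 1) = 30 rpkm
  th <- data.frame(read = 1:12, gene = "gplus", start = 1L, end = 22L,
                   antisense = TRUE)
  pl <- fake_placements(counts = rep(1L, 12), tx_hits = th, total_mapped = 1e6)
  rp <- antisense_gene_rpkm(pl, m)
  expect_equal(unname(rp["gplus"]), 12 / 0.4)
  expect_equal(unname(rp["gminus"]), 0)

  ## 300 reads, 2 kb gene, 30 M mapped -> 5.0 rpkm
  g2 <- genome_index(Biostrings::DNAStringSet(c(c1 = strrep("A", 5000))))
  m2 <- gene_models(GenomicRanges::GRangesList(
    big = GenomicRanges::GRanges("c1", IRanges::IRanges(1001, 3000),
                                 strand = "+")), g2)
  th2 <- data.frame(read = 1:300, gene = "big", start = 1L, end = 22L,
                    antisense = TRUE)
  pl2 <- fake_placements(counts = rep(1L, 300), tx_hits = th2,
                         total_mapped = 3e7)
  expect_equal(unname(antisense_gene_rpkm(pl2, m2)["big"]), 300 / (2 * 30))

  ## sense hits never count; multimapper mass splits across genes
  th3 <- data.frame(read = c(1L, 1L, 2L), gene = c("gplus", "gminus", "gplus"),
                    start = 1L, end = 22L, antisense = c(TRUE, TRUE, FALSE))
  pl3 <- fake_placements(counts = c(10L, 4L), tx_hits = th3, total_mapped = 1e6)
  rp3 <- antisense_gene_rpkm(pl3, m)
  expect_equal(unname(rp3["gplus"]), 5 / 0.4)   # half of 10 copies
  expect_equal(unname(rp3["gminus"]), 5 / 0.4)
})

test_that("rpkm is invariant to scaling all counts", {
  m <- tiny_models(tiny_genome())
  th <- data.frame(read = 1:5, gene = "gplus", start = 1L, end = 22L,
                   antisense = TRUE)
  pl_a <- fake_placements(counts = rep(2L, 5), tx_hits = th, total_mapped = 100)
  pl_b <- fake_placements(counts = rep(6L, 5), tx_hits = th, total_mapped = 300)
  expect_equal(antisense_gene_rpkm(pl_a, m), antisense_gene_rpkm(pl_b, m))
})

test_that("target calling uses a strict rpkm threshold", {
  rpkm <- matrix(c(10, 10.1, 0, 25), ncol = 2,
                 dimnames = list(c("a", "b"), c("L1", "L2")))
  t <- call_targets(rpkm, threshold = 10)
  expect_equal(t$per_library$L1, "b")     # 10.0 is not "over 10"
  expect_equal(t$per_library$L2, "b")
  expect_equal(t$union, "b")
  ## monotone non-increasing in the threshold
  sizes <- vapply(c(0, 5, 10, 20, 50),
                  function(th) length(call_targets(rpkm, th)$union), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("simulated target genes are recovered almost exactly", {
  sim <- shared_sim()
  idx <- shared_index()
  sl <- simulate_library(sim, "CSR1_like", "M3", seed = 1300)
  pl <- place_reads(sl$library, idx)
  rp <- antisense_gene_rpkm(pl, sim$models)
  called <- names(rp)[rp > 10]
  planted <- sl$truth_genes$gene[sl$truth_genes$planted_rpkm > 10]
  jac <- length(intersect(called, planted)) / length(union(called, planted))
  expect_gte(jac, 0.9)
  strong <- sl$truth_genes$gene[sl$truth_genes$planted_rpkm >= 15]
  expect_gte(mean(strong %in% called), 0.95)
})

test_that("expression groups follow the published background rule", {
  expr <- rbind(
    always = rep(20, 7),
    late = c(0, 0, 0, 0, 50, 50, 50),
    blip = c(0, 6, 0, 0, 0, 0, 0),
    border = c(5, 5, 5, 5, 5, 5, 5))   # exactly 5 rpkm counts as expressed
  colnames(expr) <- paste0("M", 1:7)
  gr <- expression_groups(expr)
  expect_equal(as.character(gr[c("always", "late", "blip", "border")]),
               c("constitutive", "meiosis_specific", "other", "constitutive"))
  expect_error(expression_groups(expr[, 1:5]), "missing stage")

  ## simulated truth: genes generated with the constitutive or
  ## meiosis-specific pattern are classified as such ("other" genes may
  ## land in any group, since their stage pattern is random)
  sim <- shared_sim()
  got <- expression_groups(sim$expression[, paste0("M", 1:7)])
  truth <- sim$truth$expression_groups
  for (gcl in c("constitutive", "meiosis_specific")) {
    expect_true(all(names(truth)[truth == gcl] %in% names(got)[got == gcl]))
  }
})

test_that("metagene profiles localize read 5' ends on transcripts", {
  g <- tiny_genome(); m <- tiny_models(g)   # mature lengths 400
  ## uniform 5' ends across the transcript -> flat profile, bias ~ 1
  n <- 10000
  set.seed(7)
  e <- sample(400, n, replace = TRUE)
  th <- data.frame(read = seq_len(n), gene = "gplus",
                   start = pmax(1L, e - 21L), end = e, antisense = TRUE)
  pl <- fake_placements(counts = rep(1L, n), tx_hits = th, total_mapped = n)
  mg <- metagene(pl, m, bins = 50)
  expect_equal(sum(mg$profile), 1, tolerance = 1e-12)
  expect_lt(abs(mg$bias - 1), 0.2)

  ## all reads at the transcript start -> capped sentinel
  th5 <- th; th5$end <- sample(40, n, replace = TRUE)
  pl5 <- fake_placements(counts = rep(1L, n), tx_hits = th5, total_mapped = n)
  mg5 <- metagene(pl5, m, bins = 50, bias_cap = 100)
  expect_equal(mg5$bias, 100)

  expect_error(metagene(pl, m, genes = character()), "empty gene set")

  ## a 5'-biased late-stage library shows a strong bias ratio
  sim <- shared_sim()
  idx <- shared_index()
  sl <- simulate_library(sim, "NRDE3_like", "M6", seed = 1500)
  plN <- place_reads(sl$library, idx)
  mgN <- metagene(plN, sim$models)
  expect_gt(mgN$bias, 2)
})

test_that("target fractions reproduce the published worked percentages", {
  univ <- sprintf("g%04d", 1:5526)
  targ <- univ[1:4910]
  expect_equal(target_fraction(targ, univ), 100 * 4910 / 5526)
  expect_equal(round(target_fraction(targ, univ)), 89)
  univ2 <- sprintf("m%04d", 1:1163)
  expect_equal(round(target_fraction(univ2[1:833], univ2)), 72)
  expect_equal(target_fraction(univ, univ), 100)
  expect_error(target_fraction(targ, character()), "empty universe")
})
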