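#' Simulation configuration
#'
#' Defines the desk-scale study conditions the synthetic genome and
#' libraries are generated under: a ~2 Mb two-contig genome plus a
#' mitochondrial contig, 300 spliced genes, a 120-locus repeat catalog
#' (dispersed TE-like families sharing a mutated consensus, plus a cold
#' 120-bp tandem family), rRNA/tRNA/miRNA loci, a planted subset of 40
#' enriched repeat loci, and 200,000-read libraries. The normalization
#' target is scaled with the genome so that mean coverage stays ~2.2x,
#' preserving the semantics of the published 20-fold and 10-fold
#' thresholds.
#'
#' @param seed Integer master seed; every output is reproducible from it.
#' @param contig_lengths Named lengths of the nuclear contigs.
#' @param mito_length Length of the mitochondrial contig.
#' @param n_genes Number of spliced genes (1-8 exons each).
#' @param n_mirna,n_rrna,n_trna Annotation locus counts.
#' @param n_dispersed_families,loci_per_family,planted_families Dispersed
#'   repeat architecture; planted families are the enriched truth subset.
#' @param n_tandem Number of (cold) tandem-repeat loci, 120-bp unit.
#' @param mutation_rate Per-base divergence of each repeat copy from its
#'   family consensus (gives multi-mapping reads).
#' @param depth Reads per library.
#' @param norm_target Coverage normalization target N0 for synthetic runs.
#' @param cold_repeat_mass Share of repeat-antisense read mass drawn from
#'   cold (non-planted) repeat loci.
#' @param first_nt_bias Probability that a read starts with the archetype's
#'   preferred nucleotide.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       contig_lengths = c(chr1 = 990000L, chr2 = 990000L),
                       mito_length = 20000L,
                       n_genes = 300L,
                       n_mirna = 30L, n_rrna = 6L, n_trna = 20L,
                       n_dispersed_families = 8L, loci_per_family = 10L,
                       planted_families = 4L, n_tandem = 40L,
                       mutation_rate = 0.02,
                       depth = 200000L,
                       norm_target = 200000,
                       cold_repeat_mass = 0.03,
                       first_nt_bias = 0.85) {
  if (depth < 1000) stopf("library depth must be >= 1000")
  stopifnot(planted_families <= n_dispersed_families, mutation_rate >= 0)
  structure(list(
    seed = as.integer(seed), contig_lengths = contig_lengths,
    mito_length = as.integer(mito_length), n_genes = as.integer(n_genes),
    n_mirna = n_mirna, n_rrna = n_rrna, n_trna = n_trna,
    n_dispersed_families = n_dispersed_families,
    loci_per_family = loci_per_family, planted_families = planted_families,
    n_tandem = n_tandem, mutation_rate = mutation_rate,
    depth = as.integer(depth), norm_target = norm_target,
    cold_repeat_mass = cold_repeat_mass, first_nt_bias = first_nt_bias,
    exons_per_gene = c(1L, 8L), exon_length = c(120L, 300L),
    intron_length = c(50L, 150L),
    planted_length = c(500L, 2000L), dispersed_length = c(500L, 3000L),
    tandem_unit = 120L, tandem_units = c(3L, 10L),
    mirna_length = c(21L, 24L), rrna_length = c(1000L, 3000L),
    trna_length = c(70L, 90L),
    locus_gap = 2200L,
    expr_meanlog = log(60), expr_sdlog = 0.7, expr_low_max = 2,
    frac_constitutive = 0.6, frac_meiosis = 0.2,
    stages = paste0("M", 1:8)),
    class = "sim_config")
}

#' Archetype table for library simulation
#'
#' One spec per Argonaute archetype: modal read length, preferred first
#' nucleotide and bias, early and late target mixtures, stage at which the
#' late mixture starts, per-stage depth factors, and whether late-stage
#' antisense reads are 5'-biased on the transcript. Mixtures are
#' proportions over read source components (miRNA, repeat-antisense,
#' mRNA-antisense, mRNA-sense, intergenic, rRNA, tRNA, random sequence)
#' and sum to 1.
#'
#' * input: 22 nt, G-start; 85% repeat-antisense (the published 80-90%
#'   bulk of total small RNAs).
#' * ALG1_like: 22 nt, U-start miRNA reads.
#' * ALG4_like: 26 nt; input-like until M5, then mRNA-antisense reads from
#'   meiosis-specific genes at full depth in M6-M7.
#' * WAGO12_like: 22 nt G; repeat-dominant in all stages.
#' * CSR1_like: 24 nt, G-start with a 20-25% adenine minority;
#'   mRNA-antisense to expressed genes, weight proportional to expression.
#' * NRDE3_like: 22 nt G; repeat-dominant early, switching to mRNA at M5,
#'   with a 5' bias on transcripts.
#' * WAGO3_like: 23 nt G; repeats in germline, mRNAs late.
#'
#' @param cfg A [sim_config] (supplies the first-nucleotide bias).
#' @return Named list of archetype specs.
#' @export
archetype_table <- function(cfg = sim_config()) {
  b <- cfg$first_nt_bias
  rest <- (1 - b) / 3
  gbias <- c(A = rest, C = rest, G = b, U = rest)
  ubias <- c(A = rest, C = rest, G = rest, U = b)
  csr <- c(A = 0.22, C = 0.06, G = 0.60, U = 0.12)
  mix <- function(...) {
    m <- c(...)
    stopifnot(abs(sum(m) - 1) < 1e-9)
    m
  }
  input_mix <- mix(repeat_antisense = 0.85, mrna_antisense = 0.05,
                   mirna = 0.02, rrna = 0.02, trna = 0.01,
                   mrna_sense = 0.02, intergenic = 0.03)
  list(
    input = list(name = "input", length_mode = 22L, nt_prob = gbias,
                 early = input_mix, late = input_mix, late_from = 99L,
                 pool = "expressed", five_prime_bias = FALSE),
    ALG1_like = list(name = "ALG1_like", length_mode = 22L, nt_prob = ubias,
                     early = mix(mirna = 0.85, mrna_sense = 0.03,
                                 repeat_antisense = 0.05, intergenic = 0.03,
                                 rrna = 0.02, trna = 0.02),
                     late = NULL, late_from = 99L,
                     pool = "expressed", five_prime_bias = FALSE),
    ALG4_like = list(name = "ALG4_like", length_mode = 26L, nt_prob = gbias,
                     early = input_mix,
                     late = mix(mrna_antisense = 0.85, repeat_antisense = 0.05,
                                mirna = 0.01, intergenic = 0.04,
                                mrna_sense = 0.03, rrna = 0.01, trna = 0.01),
                     late_from = 6L, pool = "meiosis",
                     five_prime_bias = FALSE,
                     depth_factor = c(M1 = 0.002, M2 = 0.002, M3 = 0.002,
                                      M4 = 0.002, M5 = 0.002)),
    WAGO12_like = list(name = "WAGO12_like", length_mode = 22L, nt_prob = gbias,
                       early = mix(repeat_antisense = 0.85,
                                   mrna_antisense = 0.06, intergenic = 0.04,
                                   mrna_sense = 0.02, rrna = 0.02, trna = 0.01),
                       late = NULL, late_from = 99L,
                       pool = "expressed", five_prime_bias = FALSE),
    CSR1_like = list(name = "CSR1_like", length_mode = 24L, nt_prob = csr,
                     early = mix(mrna_antisense = 0.85,
                                 repeat_antisense = 0.07, intergenic = 0.03,
                                 mrna_sense = 0.03, rrna = 0.01, trna = 0.01),
                     late = NULL, late_from = 99L,
                     pool = "expressed", five_prime_bias = FALSE),
    NRDE3_like = list(name = "NRDE3_like", length_mode = 22L, nt_prob = gbias,
                      early = mix(repeat_antisense = 0.75,
                                  mrna_antisense = 0.10, intergenic = 0.05,
                                  mrna_sense = 0.04, mirna = 0.02,
                                  rrna = 0.02, trna = 0.02),
                      late = mix(repeat_antisense = 0.25,
                                 mrna_antisense = 0.60, intergenic = 0.05,
                                 mrna_sense = 0.04, mirna = 0.02,
                                 rrna = 0.02, trna = 0.02),
                      late_from = 5L, pool = "expressed",
                      five_prime_bias = TRUE),
    WAGO3_like = list(name = "WAGO3_like", length_mode = 23L, nt_prob = gbias,
                      early = mix(repeat_antisense = 0.80,
                                  mrna_antisense = 0.08, intergenic = 0.05,
                                  mrna_sense = 0.03, rrna = 0.02, trna = 0.02),
                      late = mix(mrna_antisense = 0.70,
                                 repeat_antisense = 0.15, intergenic = 0.06,
                                 mrna_sense = 0.05, rrna = 0.02, trna = 0.02),
                      late_from = 8L, pool = "expressed",
                      five_prime_bias = FALSE))
}

## The flat mixture used for M8 spermatid libraries: no component dominates
## after classification, and lengths are uniform over 18-30 nt.
noise_mixture <- function() {
  c(mirna = 0.125, repeat_antisense = 0.125, mrna_antisense = 0.125,
    mrna_sense = 0.125, intergenic = 0.125, rrna = 0.125, trna = 0.125,
    random = 0.125)
}

mutate_bases <- function(bases, rate) {
  hit <- which(runif(length(bases)) < rate)
  if (length(hit)) {
    ## shift each hit base by 1-3 positions around the A/C/G/T cycle
    alphabet <- c("A", "C", "G", "T")
    cur <- match(bases[hit], alphabet)
    bases[hit] <- alphabet[((cur - 1L + sample.int(3L, length(hit),
                                                   replace = TRUE)) %% 4L) + 1L]
  }
  bases
}

#' Generate a synthetic genome with annotations, expression and truth
#'
#' Builds the genome sequence (i.i.d. uniform bases except repeat loci,
#' which reuse a family consensus with per-copy mutation so multi-mapping
#' reads exist), places non-overlapping features with a minimum gap,
#' assigns per-gene per-stage expression (log-normal for expressed
#' gene-stages, near zero otherwise, in constitutive / meiosis-specific /
#' other patterns), and records ground truth.
#'
#' @param cfg A [sim_config].
#' @return A list of class `sim_genome`: `genome` ([genome_index]),
#'   `models`, `annotations`, `expression` (genes x M1-M8 rpkm matrix),
#'   `truth` (planted repeat loci, expected fold, expression groups),
#'   `contig_strings` (cached sequence for fast read sampling),
#'   `tx_strings`, `intergenic` (`GRanges` of unannotated space), `config`.
#' @export
generate_genome <- function(cfg = sim_config()) {
  local_seed(cfg$seed, {
    chrs <- names(cfg$contig_lengths)
    lens <- c(cfg$contig_lengths, mito = cfg$mito_length)
    bases <- lapply(lens, function(L) sample(c("A", "C", "G", "T"), L, replace = TRUE))
    names(bases) <- names(lens)

    ## free-space allocator: features are carved out of per-contig free
    ## intervals with a half-margin on each side, so any two features end
    ## up > merge_dist apart and placement always succeeds if space exists
    free <- lapply(cfg$contig_lengths, function(L) data.frame(start = 1L, end = L))
    big_margin <- as.integer(ceiling(cfg$locus_gap / 2))
    place <- function(n, len_fun, label, margin = 25L) {
      out_chr <- character(n); out_st <- integer(n); out_L <- integer(n)
      for (i in seq_len(n)) {
        L <- len_fun()
        need <- L + 2L * margin
        cands <- do.call(rbind, lapply(chrs, function(ch) {
          fr <- free[[ch]]
          w <- fr$end - fr$start + 1L
          ok <- which(w >= need)
          if (!length(ok)) return(NULL)
          data.frame(chr = ch, idx = ok, slots = w[ok] - need + 1)
        }))
        if (is.null(cands))
          stopf("genome too small to place %s feature %d (need %d bp incl. margins)",
                label, i, need)
        pick <- cands[sample.int(nrow(cands), 1, prob = cands$slots), ]
        fr <- free[[pick$chr]][pick$idx, ]
        o <- floor(runif(1) * (fr$end - fr$start + 2L - need))
        fs <- fr$start + o
        newfree <- rbind(
          if (o > 0) data.frame(start = fr$start, end = fs - 1L),
          if (fs + need <= fr$end) data.frame(start = fs + need, end = fr$end))
        free[[pick$chr]] <<- rbind(free[[pick$chr]][-pick$idx, , drop = FALSE],
                                   newfree)
        out_chr[i] <- pick$chr; out_st[i] <- as.integer(fs + margin)
        out_L[i] <- L
      }
      data.frame(chr = out_chr, start = out_st, width = out_L,
                 strand = sample(c("+", "-"), n, replace = TRUE))
    }
    as_gr <- function(df) GenomicRanges::GRanges(
      df$chr, IRanges::IRanges(df$start, width = df$width), strand = df$strand)

    runifint <- function(r) function() sample(seq.int(r[1], r[2]), 1)
    ## blacklist-class loci keep the large margin too: a high-coverage
    ## window inside one must never merge (within merge_dist) into a called
    ## repeat locus, or the blacklist filter would eat a true positive
    rrna_df <- place(cfg$n_rrna, runifint(cfg$rrna_length), "rRNA",
                     margin = big_margin)
    trna_df <- place(cfg$n_trna, runifint(cfg$trna_length), "tRNA",
                     margin = big_margin)
    mirna_df <- place(cfg$n_mirna, runifint(cfg$mirna_length), "miRNA",
                      margin = big_margin)
    ## give every miRNA locus a 5' U (T on the sense strand)
    for (i in seq_len(nrow(mirna_df))) {
      chr <- mirna_df$chr[i]
      if (mirna_df$strand[i] == "+") {
        bases[[chr]][mirna_df$start[i]] <- "T"
      } else {
        bases[[chr]][mirna_df$start[i] + mirna_df$width[i] - 1L] <- "A"
      }
    }
    rrna <- as_gr(rrna_df); trna <- as_gr(trna_df); mirna <- as_gr(mirna_df)

    ## genes: place the span, then carve exons/introns inside it
    gene_ids <- sprintf("gene_%03d", seq_len(cfg$n_genes))
    ex_chr <- character(0); ex_start <- integer(0); ex_len <- integer(0)
    ex_strand <- character(0); ex_gene <- character(0)
    span_df <- vector("list", cfg$n_genes)
    for (g in seq_len(cfg$n_genes)) {
      ne <- sample(seq.int(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1)
      elens <- sample(seq.int(cfg$exon_length[1], cfg$exon_length[2]), ne,
                      replace = TRUE)
      ilens <- if (ne > 1)
        sample(seq.int(cfg$intron_length[1], cfg$intron_length[2]), ne - 1,
               replace = TRUE) else integer()
      span <- sum(elens) + sum(ilens)
      sp <- place(1, function() span, "gene")
      starts <- sp$start + cumsum(c(0L, head(elens, -1L) + ilens))
      ex_chr <- c(ex_chr, rep(sp$chr, ne))
      ex_start <- c(ex_start, starts)
      ex_len <- c(ex_len, elens)
      ex_strand <- c(ex_strand, rep(sp$strand, ne))
      ex_gene <- c(ex_gene, rep(gene_ids[g], ne))
      span_df[[g]] <- sp
    }
    exons_gr <- GenomicRanges::GRanges(
      ex_chr, IRanges::IRanges(ex_start, width = ex_len), strand = ex_strand)
    exon_grl <- GenomicRanges::split(exons_gr,
                                     factor(ex_gene, levels = gene_ids))
    gene_spans <- as_gr(do.call(rbind, span_df))

    ## repeats: dispersed consensus families + cold tandem family
    fam_consensus <- lapply(seq_len(cfg$n_dispersed_families), function(f)
      sample(c("A", "C", "G", "T"), max(cfg$dispersed_length), replace = TRUE))
    tandem_consensus <- sample(c("A", "C", "G", "T"), cfg$tandem_unit,
                               replace = TRUE)
    rep_df <- list(); rep_meta <- list()
    write_copy <- function(loc, copy) {
      if (loc$strand == "-") copy <- rev(chartr("ACGT", "TGCA", copy))
      bases[[loc$chr]][seq.int(loc$start, loc$start + loc$width - 1L)] <<- copy
    }
    for (f in seq_len(cfg$n_dispersed_families)) {
      planted <- f <= cfg$planted_families
      lr <- if (planted) cfg$planted_length else cfg$dispersed_length
      for (j in seq_len(cfg$loci_per_family)) {
        loc <- place(1, runifint(lr), "repeat", margin = big_margin)
        write_copy(loc, mutate_bases(fam_consensus[[f]][seq_len(loc$width)],
                                     cfg$mutation_rate))
        rep_df[[length(rep_df) + 1L]] <- loc
        rep_meta[[length(rep_meta) + 1L]] <-
          data.frame(family = sprintf("DTE%02d", f), planted = planted,
                     type = "dispersed")
      }
    }
    for (j in seq_len(cfg$n_tandem)) {
      nu <- sample(seq.int(cfg$tandem_units[1], cfg$tandem_units[2]), 1)
      loc <- place(1, function() nu * cfg$tandem_unit, "tandem repeat",
                   margin = big_margin)
      write_copy(loc, mutate_bases(rep(tandem_consensus, nu), cfg$mutation_rate))
      rep_df[[length(rep_df) + 1L]] <- loc
      rep_meta[[length(rep_meta) + 1L]] <-
        data.frame(family = "TAND", planted = FALSE, type = "tandem")
    }
    repeats <- as_gr(do.call(rbind, rep_df))
    meta <- do.call(rbind, rep_meta)
    S4Vectors::mcols(repeats)$name <- sprintf("rep_%03d", seq_along(repeats))
    S4Vectors::mcols(repeats)$family <- meta$family
    S4Vectors::mcols(repeats)$planted <- meta$planted
    S4Vectors::mcols(repeats)$type <- meta$type

    contig_strings <- vapply(bases, paste, "", collapse = "")
    genome <- genome_index(
      Biostrings::DNAStringSet(contig_strings), mito_contigs = "mito")
    models <- gene_models(exon_grl, genome)
    set_names_class <- function(gr, prefix, cl) {
      S4Vectors::mcols(gr)$name <- sprintf("%s_%03d", prefix, seq_along(gr))
      S4Vectors::mcols(gr)$class <- cl
      gr
    }
    ann <- annotation_bundle(genome, models,
                             rRNA = set_names_class(rrna, "rrna", "rRNA"),
                             tRNA = set_names_class(trna, "trna", "tRNA"),
                             miRNA = set_names_class(mirna, "mirna", "miRNA"),
                             repeats = repeats)

    ## expression: constitutive / meiosis-specific / other patterns
    grp <- sample(rep(c("constitutive", "meiosis_specific", "other"),
                      times = round(cfg$n_genes *
                                      c(cfg$frac_constitutive, cfg$frac_meiosis,
                                        1 - cfg$frac_constitutive - cfg$frac_meiosis)))[
                                          seq_len(cfg$n_genes)])
    expr <- matrix(0, cfg$n_genes, 8, dimnames = list(gene_ids, cfg$stages))
    hi <- function(n) pmax(5.5, rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog))
    lo <- function(n) runif(n, 0, cfg$expr_low_max)
    for (s in 1:7) {
      on <- (grp == "constitutive") |
        (grp == "meiosis_specific" & s >= 5) |
        (grp == "other" & runif(cfg$n_genes) < 0.35)
      expr[on, s] <- hi(sum(on))
      expr[!on, s] <- lo(sum(!on))
    }
    expr[, 8] <- lo(cfg$n_genes)

    occupied <- suppressWarnings(GenomicRanges::reduce(c(
      GenomicRanges::granges(rrna), GenomicRanges::granges(trna),
      GenomicRanges::granges(mirna), GenomicRanges::granges(repeats),
      GenomicRanges::granges(gene_spans)),
      ignore.strand = TRUE))
    GenomicRanges::strand(occupied) <- "*"
    GenomeInfoDb::seqlevels(occupied) <- names(lens)
    intergenic <- GenomicRanges::gaps(
      GenomicRanges::reduce(occupied, ignore.strand = TRUE),
      end = setNames(as.integer(lens), names(lens)))
    intergenic <- intergenic[as.character(GenomicRanges::strand(intergenic)) == "*"]
    intergenic <- intergenic[as.character(GenomicRanges::seqnames(intergenic)) != "mito"]
    intergenic <- GenomicRanges::resize(
      intergenic, pmax(1L, GenomicRanges::width(intergenic) - 100L), fix = "center")
    intergenic <- intergenic[GenomicRanges::width(intergenic) >= 60]

    planted <- repeats[S4Vectors::mcols(repeats)$planted]
    txs <- transcript_seqs(models, genome)
    structure(list(
      genome = genome, models = models, annotations = ann,
      expression = expr,
      truth = list(
        planted_repeats = planted,
        expected_planted_fold =
          0.85 * (1 - cfg$cold_repeat_mass) *
          sum(as.numeric(cfg$contig_lengths)) /
          sum(as.numeric(GenomicRanges::width(planted))),
        expression_groups = factor(setNames(grp, gene_ids),
                                   levels = c("constitutive", "meiosis_specific",
                                              "other"))),
      contig_strings = contig_strings,
      tx_strings = setNames(as.character(txs), names(txs)),
      intergenic = intergenic,
      config = cfg),
      class = "sim_genome")
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf(
    "sim_genome: %s bp, %d genes, %d repeat loci (%d planted), seed %d\n",
    format(sum(as.numeric(x$genome$lengths)), big.mark = ","),
    length(x$models$gene_id), length(x$annotations$repeats),
    sum(S4Vectors::mcols(x$annotations$repeats)$planted), x$config$seed))
  invisible(x)
}
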