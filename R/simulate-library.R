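## Read samplers used by simulate_library(). All sequences are returned as
## DNA (A/C/G/T) character vectors; "first nucleotide" targets arrive as
## DNA too (U already mapped to T).

## Sample reads lying wholly inside genomic regions. orientation "sense"
## reads the region's own strand, "antisense" its reverse complement.
## nt_target, when given, is enforced by bounded rejection sampling on the
## read's first base.
sample_genomic_reads <- function(sim, regions, n, lens, orientation,
                                 nt_target = NULL, region_idx = NULL,
                                 rounds = 16L) {
  if (n == 0) return(character())
  ridx <- region_idx %||%
    sample.int(length(regions), n, replace = TRUE,
               prob = GenomicRanges::width(regions))
  chr <- as.character(GenomicRanges::seqnames(regions))[ridx]
  rs <- GenomicRanges::start(regions)[ridx]
  re <- GenomicRanges::end(regions)[ridx]
  rstrand <- as.character(GenomicRanges::strand(regions))[ridx]
  rstrand[rstrand == "*"] <- "+"
  L <- pmin(lens, re - rs + 1L)
  top <- (orientation == "sense") == (rstrand == "+")
  ctg <- sim$contig_strings[chr]
  pos <- integer(n); need <- rep(TRUE, n)
  for (round in seq_len(rounds)) {
    if (!any(need)) break
    i <- which(need)
    p <- rs[i] + floor(runif(length(i)) * (re[i] - rs[i] - L[i] + 2))
    if (is.null(nt_target)) { pos[i] <- p; need[i] <- FALSE; next }
    fb_pos <- ifelse(top[i], p, p + L[i] - 1L)
    fb <- substring(ctg[i], fb_pos, fb_pos)
    fb <- ifelse(top[i], fb, chartr("ACGT", "TGCA", fb))
    ok <- fb == nt_target[i] | round == rounds
    pos[i[ok]] <- p[ok]
    need[i[ok]] <- FALSE
  }
  seqs <- substring(ctg, pos, pos + L - 1L)
  flip <- !top
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
  seqs
}

## Sample reads against spliced transcripts (so reads can span junctions).
## Antisense reads: the read 5' end pairs with transcript position e; with
## five_bias the e positions concentrate near the transcript 5' end
## (Beta(1,3) on the relative position).
sample_tx_reads <- function(sim, gene_ids, weights, n, lens,
                            antisense = TRUE, five_bias = FALSE,
                            nt_target = NULL, rounds = 16L) {
  if (n == 0) return(list(seqs = character(), gene = character()))
  gidx <- sample.int(length(gene_ids), n, replace = TRUE, prob = weights)
  gid <- gene_ids[gidx]
  txlen <- unname(sim$models$mature_length[gid])
  tx <- sim$tx_strings[gid]
  L <- pmin(lens, txlen)
  pos <- integer(n); need <- rep(TRUE, n)
  draw_anchor <- function(k, Lk, lenk) {
    if (antisense) {
      if (five_bias) pmax(Lk, ceiling(stats::rbeta(k, 1, 3) * lenk))
      else Lk + floor(runif(k) * (lenk - Lk + 1))
    } else {
      1L + floor(runif(k) * (lenk - Lk + 1))
    }
  }
  for (round in seq_len(rounds)) {
    if (!any(need)) break
    i <- which(need)
    p <- draw_anchor(length(i), L[i], txlen[i])
    if (is.null(nt_target)) { pos[i] <- p; need[i] <- FALSE; next }
    fb <- substring(tx[i], p, p)
    if (antisense) fb <- chartr("ACGT", "TGCA", fb)
    ok <- fb == nt_target[i] | round == rounds
    pos[i[ok]] <- p[ok]
    need[i[ok]] <- FALSE
  }
  seqs <- if (antisense) revcomp(substring(tx, pos - L + 1L, pos))
          else substring(tx, pos, pos + L - 1L)
  list(seqs = seqs, gene = gid)
}

## Mature miRNA reads: sense reads anchored at the locus 5' end (small
## offset jitter); the genome guarantees a 5' U there.
sample_mirna_reads <- function(sim, n, lens) {
  if (n == 0) return(character())
  loci <- sim$annotations$miRNA
  ridx <- sample.int(length(loci), n, replace = TRUE)
  offset <- sample(0:2, n, replace = TRUE, prob = c(0.8, 0.15, 0.05))
  w <- GenomicRanges::width(loci)[ridx]
  L <- pmin(lens, w - offset)
  chr <- as.character(GenomicRanges::seqnames(loci))[ridx]
  plus <- as.character(GenomicRanges::strand(loci))[ridx] == "+"
  st <- ifelse(plus, GenomicRanges::start(loci)[ridx] + offset,
               GenomicRanges::end(loci)[ridx] - offset - L + 1L)
  seqs <- substring(sim$contig_strings[chr], st, st + L - 1L)
  seqs[!plus] <- revcomp(seqs[!plus])
  seqs
}

random_reads <- function(n, lens) {
  if (n == 0) return(character())
  out <- character(n)
  for (L in unique(lens)) {
    i <- which(lens == L)
    m <- matrix(sample(c("A", "C", "G", "T"), length(i) * L, replace = TRUE),
                nrow = length(i))
    out[i] <- apply(m, 1, paste, collapse = "")
  }
  out
}

## Gene pool for the mRNA components of an archetype in a given stage.
gene_pool <- function(sim, pool, stage, noise = FALSE) {
  if (noise)
    return(list(genes = sim$models$gene_id,
                weights = rep(1, length(sim$models$gene_id))))
  if (!stage %in% colnames(sim$expression))
    stopf("unknown stage '%s'", stage)
  e <- sim$expression[, stage]
  keep <- e >= 5
  if (pool == "meiosis")
    keep <- keep & sim$truth$expression_groups == "meiosis_specific"
  if (!any(keep))
    stopf("no genes available for the mRNA component in stage %s", stage)
  list(genes = names(e)[keep], weights = unname(e[keep]))
}

#' Simulate one Argonaute-IP small-RNA library
#'
#' Draws `depth` reads from the archetype's target mixture for the given
#' stage: read lengths follow a discretized Normal(mode, 1) clipped to
#' 18-30 nt, the first nucleotide follows the archetype bias, repeat
#' antisense reads come from planted loci (with a small cold-locus share),
#' mRNA-antisense reads come from spliced transcripts with copy numbers
#' proportional to gene expression, and M8 libraries use a flat noise
#' mixture with uniform lengths. Every sampled read carries a ground-truth
#' category label.
#'
#' @param sim A [generate_genome()] result.
#' @param archetype Archetype name (see [archetype_table()]) or a spec.
#' @param stage Stage label, one of the config's stages (M1-M8).
#' @param depth Reads to draw before the archetype's per-stage depth
#'   factor (default: config depth). Must be positive.
#' @param seed Seed for this library (default: config seed).
#' @return A list of class `sim_library`: `library` (an [srna_library]),
#'   `truth_reads` (per distinct sequence: truth category and copies),
#'   `truth_genes` (per gene: antisense copies and planted rpkm),
#'   `mixture`, `archetype`, `stage`, `depth`.
#' @export
simulate_library <- function(sim, archetype, stage = "M1",
                             depth = NULL, seed = NULL) {
  cfg <- sim$config
  depth <- depth %||% cfg$depth
  seed <- seed %||% cfg$seed
  spec <- if (is.character(archetype)) {
    tab <- archetype_table(cfg)
    if (!archetype %in% names(tab)) stopf("unknown archetype '%s'", archetype)
    tab[[archetype]]
  } else archetype
  if (depth <= 0) stopf("depth must be positive")
  sidx <- match(stage, cfg$stages)
  noise <- !is.na(sidx) && stage == "M8"
  late <- !is.na(sidx) && !is.null(spec$late) && sidx >= spec$late_from
  mixture <- if (noise) noise_mixture() else if (late) spec$late else spec$early
  df_tab <- spec$depth_factor
  dfac <- if (noise || is.null(df_tab) || !stage %in% names(df_tab)) 1
          else df_tab[[stage]]
  depth_eff <- max(1L, as.integer(round(depth * unname(dfac))))
  lib_id <- paste(stage, spec$name, sep = "_")

  local_seed(seed, {
    comp_n <- as.integer(rmultinom(1, depth_eff, mixture)[, 1])
    names(comp_n) <- names(mixture)
    lens_all <- if (noise) sample(18:30, depth_eff, replace = TRUE)
      else pmin(30L, pmax(18L, as.integer(round(rnorm(depth_eff,
                                                      spec$length_mode, 1)))))
    nt_all <- chartr("U", "T",
                     sample(names(spec$nt_prob), depth_eff, replace = TRUE,
                            prob = spec$nt_prob))
    off <- cumsum(c(0L, comp_n))
    take <- function(k, j) if (comp_n[j] == 0) integer() else
      seq.int(off[j] + 1L, off[j] + comp_n[j])

    seqs <- character(depth_eff)
    label <- character(depth_eff)
    gene_of <- rep(NA_character_, depth_eff)
    reps <- sim$annotations$repeats
    planted <- reps[S4Vectors::mcols(reps)$planted]
    cold <- reps[!S4Vectors::mcols(reps)$planted]

    for (j in seq_along(comp_n)) {
      comp <- names(comp_n)[j]
      idx <- take(comp_n[j], j)
      if (!length(idx)) next
      lens <- lens_all[idx]; nts <- nt_all[idx]
      out <- switch(
        comp,
        mirna = {
          label[idx] <- "miRNA"
          sample_mirna_reads(sim, length(idx), lens)
        },
        repeat_antisense = {
          label[idx] <- "WAGO_repeats"
          n_cold <- rbinom(1, length(idx), cfg$cold_repeat_mass)
          pc <- c(rep(FALSE, n_cold), rep(TRUE, length(idx) - n_cold))
          s <- character(length(idx))
          s[pc] <- sample_genomic_reads(sim, planted, sum(pc), lens[pc],
                                        "antisense", nts[pc])
          s[!pc] <- sample_genomic_reads(sim, cold, sum(!pc), lens[!pc],
                                         "antisense", nts[!pc])
          s
        },
        mrna_antisense = {
          label[idx] <- "antisense_mRNA"
          ## archetype-specific pools (e.g. meiosis genes for ALG4-like)
          ## apply to the late mixture; early mixtures draw from whatever
          ## is expressed in the stage
          pool <- gene_pool(sim, if (late) spec$pool else "expressed",
                            stage, noise)
          r <- sample_tx_reads(sim, pool$genes, pool$weights, length(idx),
                               lens, antisense = TRUE,
                               five_bias = isTRUE(spec$five_prime_bias) && late,
                               nt_target = nts)
          gene_of[idx] <- r$gene
          r$seqs
        },
        mrna_sense = {
          label[idx] <- "sense_mRNA"
          pool <- gene_pool(sim, "expressed", stage, noise)
          r <- sample_tx_reads(sim, pool$genes, pool$weights, length(idx),
                               lens, antisense = FALSE)
          r$seqs
        },
        intergenic = {
          label[idx] <- "intergenic"
          sample_genomic_reads(sim, sim$intergenic, length(idx), lens,
                               "antisense", nts)
        },
        rrna = {
          label[idx] <- "rRNA"
          sample_genomic_reads(sim, sim$annotations$rRNA, length(idx), lens,
                               "sense")
        },
        trna = {
          label[idx] <- "tRNA"
          sample_genomic_reads(sim, sim$annotations$tRNA, length(idx), lens,
                               "sense")
        },
        random = {
          label[idx] <- "no_match"
          random_reads(length(idx), lens)
        },
        stopf("unknown mixture component '%s'", comp))
      seqs[idx] <- out
    }

    lib <- srna_library(seqs, 1L, id = lib_id, stage = stage,
                        argonaute = spec$name)
    key <- paste(label, seqs, sep = "\t")
    cnt <- rowsum(rep(1L, depth_eff), key)
    parts <- strsplit(rownames(cnt), "\t", fixed = TRUE)
    tr <- data.frame(seq = vapply(parts, `[[`, "", 2L),
                     truth = vapply(parts, `[[`, "", 1L),
                     copies = as.integer(cnt[, 1]))
    anti <- which(label == "antisense_mRNA")
    tg <- if (length(anti)) {
      tab <- table(gene_of[anti])
      data.frame(gene = names(tab), antisense_copies = as.integer(tab),
                 planted_rpkm = as.integer(tab) /
                   (unname(sim$models$mature_length[names(tab)]) / 1e3 *
                      depth_eff / 1e6),
                 row.names = NULL)
    } else data.frame(gene = character(), antisense_copies = integer(),
                      planted_rpkm = numeric())
    structure(list(library = lib, truth_reads = tr, truth_genes = tg,
                   mixture = mixture, archetype = spec$name, stage = stage,
                   depth = depth_eff),
              class = "sim_library")
  })
}

#' Simulate a full stage series of libraries
#'
#' Generates one library per (stage, archetype) pair across M1-M8. The
#' ALG4-like archetype runs at ~0.2% depth before M6 (26G-RNAs only appear
#' in late meiosis); the NRDE3-like archetype switches its mixture from
#' repeats to mRNAs at M5; every archetype's M8 library is the flat noise
#' mixture with a flat length distribution.
#'
#' @param sim A [generate_genome()] result.
#' @param archetypes Archetype names to simulate.
#' @param stages Stage labels (default M1-M8).
#' @param depth Per-library depth before depth factors.
#' @param seed Base seed; per-library seeds are small deterministic
#'   offsets from it.
#' @return Named list of `sim_library` objects, names `<stage>_<archetype>`.
#' @export
stage_series <- function(sim,
                         archetypes = c("input", "WAGO12_like", "CSR1_like",
                                        "NRDE3_like", "ALG4_like"),
                         stages = sim$config$stages,
                         depth = NULL, seed = NULL) {
  seed <- seed %||% sim$config$seed
  out <- list()
  for (si in seq_along(stages)) {
    for (ai in seq_along(archetypes)) {
      sl <- simulate_library(sim, archetypes[ai], stages[si],
                             depth = depth,
                             seed = seed + 97L * si + 1013L * ai)
      out[[paste(stages[si], archetypes[ai], sep = "_")]] <- sl
    }
  }
  out
}

#' Write a simulated data set to disk
#'
#' Emits `genome.fa`, `genes.gff3`, the annotation BEDs (`rrna.bed`,
#' `trna.bed`, `mirna.bed`, `repeats.bed`), `expression.tsv`, truth tables
#' (`truth_planted_repeats.bed`, `truth_expression_groups.tsv`), and for
#' each supplied library a FASTQ, a collapsed FASTA and a per-read truth
#' TSV.
#'
#' @param sim A [generate_genome()] result.
#' @param libs Optional named list of `sim_library` objects.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, libs = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_fasta_genome(sim$genome, p("genome.fa"))
  write_gff3_genes(sim$models, p("genes.gff3"))
  write_bed(sim$annotations$rRNA, p("rrna.bed"))
  write_bed(sim$annotations$tRNA, p("trna.bed"))
  write_bed(sim$annotations$miRNA, p("mirna.bed"))
  write_bed(sim$annotations$repeats, p("repeats.bed"))
  write_bed(sim$truth$planted_repeats, p("truth_planted_repeats.bed"))
  write.table(data.frame(gene = rownames(sim$expression), sim$expression,
                         group = sim$truth$expression_groups),
              p("expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(libs)) {
    write_fastq(libs[[nm]]$library, p(paste0(nm, ".fastq")))
    write_collapsed_fasta(libs[[nm]]$library, p(paste0(nm, ".collapsed.fa")))
    write.table(libs[[nm]]$truth_reads, p(paste0(nm, ".truth.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
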