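#' Gene models
#'
#' A set of spliced gene models: per-gene exon ranges, derived introns, and
#' mature (spliced) transcript lengths. The mature-transcript coordinate
#' system (1..mature length, 5' to 3' of the mRNA) is what antisense target
#' calling and metagene profiling operate in.
#'
#' @param exons A named [GenomicRanges::GRangesList], one element per gene,
#'   holding that gene's exons. Each element must be single-contig,
#'   single-strand (`+` or `-`), non-overlapping.
#' @param genome Optional [genome_index]; if given, exons are checked to lie
#'   within their contig.
#' @return An object of class `gene_models` with elements `gene_id`,
#'   `exons` (coordinate-sorted `GRangesList`), `introns` (`GRangesList` of
#'   inter-exon gaps), `strand` and `mature_length` (named vectors).
#' @export
gene_models <- function(exons, genome = NULL) {
  if (!is(exons, "GRangesList")) stopf("`exons` must be a GRangesList")
  ids <- names(exons)
  if (length(exons) == 0) {
    empty <- GenomicRanges::GRangesList()
    return(structure(list(gene_id = character(), exons = exons,
                          introns = empty,
                          strand = setNames(character(), character()),
                          mature_length = setNames(integer(), character())),
                     class = "gene_models"))
  }
  if (is.null(ids) || anyDuplicated(ids)) stopf("gene ids must be unique names")
  unl <- unlist(exons, use.names = FALSE)
  g <- rep(ids, S4Vectors::elementNROWS(exons))
  gf <- factor(g, levels = ids)
  chr <- as.character(GenomicRanges::seqnames(unl))
  str <- as.character(GenomicRanges::strand(unl))
  one <- function(x) vapply(split(x, gf), function(v)
    length(unique(v)) == 1L, TRUE)
  if (any(!one(chr)) || any(!one(str)))
    stopf("gene %s: exons must share one contig and one strand",
          ids[which(!one(chr) | !one(str))[1]])
  strand <- vapply(split(str, gf), `[[`, "", 1L)
  if (any(!strand %in% c("+", "-")))
    stopf("gene %s: strand must be + or -", ids[!strand %in% c("+", "-")][1])
  ord <- order(as.integer(gf), GenomicRanges::start(unl))
  unl <- unl[ord]; gf <- gf[ord]
  st <- GenomicRanges::start(unl); en <- GenomicRanges::end(unl)
  same <- as.integer(gf[-1]) == as.integer(gf[-length(gf)])
  if (length(st) > 1 && any(same & st[-1] <= en[-length(en)]))
    stopf("gene %s: overlapping exons",
          as.character(gf[-1])[same & st[-1] <= en[-length(en)]][1])
  if (!is.null(genome)) {
    bad <- setdiff(chr, names(genome$lengths))
    if (length(bad)) stopf("gene on unknown contig: %s", bad[1])
    over <- GenomicRanges::end(unl) >
      genome$lengths[as.character(GenomicRanges::seqnames(unl))]
    if (any(over)) stopf("gene %s: exon beyond contig end",
                         as.character(gf)[over][1])
  }
  mature <- vapply(split(GenomicRanges::width(unl), gf), sum, 0)
  if (any(mature == 0)) stopf("gene %s: mature length 0", ids[mature == 0][1])
  exons_sorted <- GenomicRanges::split(unl, gf)
  ## introns = gaps between consecutive exons of the same gene
  gap_ok <- which(same & st[-1] > en[-length(en)] + 1L)
  intr <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(unl))[gap_ok],
    IRanges::IRanges(en[gap_ok] + 1L, st[gap_ok + 1L] - 1L),
    strand = as.character(GenomicRanges::strand(unl))[gap_ok])
  introns <- GenomicRanges::split(intr, factor(as.character(gf)[gap_ok],
                                               levels = ids))
  structure(
    list(gene_id = ids, exons = exons_sorted, introns = introns,
         strand = setNames(strand, ids),
         mature_length = setNames(as.integer(mature), ids)),
    class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, mature length %d-%d bp (median %d)\n",
              length(x$gene_id), min(x$mature_length), max(x$mature_length),
              as.integer(stats::median(x$mature_length))))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Expects gene/mRNA/exon features with `Parent` attributes linking exons to
#' mRNAs. GFF3 1-based inclusive coordinates map directly onto the internal
#' `GRanges` convention. One gene model is built per mRNA; mRNAs without
#' exons are skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @param genome A [genome_index] used to validate coordinates.
#' @return A [gene_models] object.
#' @export
read_gff3_genes <- function(path, genome) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  mrna <- gff[type == "mRNA"]
  ex <- gff[type == "exon"]
  if (length(mrna) == 0) {
    return(gene_models(GenomicRanges::GRangesList(), genome))
  }
  parent <- as.character(S4Vectors::unstrsplit(ex$Parent, ","))
  keep <- parent %in% mrna$ID
  ex <- ex[keep]; parent <- parent[keep]
  exl <- GenomicRanges::split(GenomicRanges::granges(ex), factor(parent, levels = mrna$ID))
  empty <- lengths(exl) == 0
  if (any(empty)) {
    warnf("%d mRNA(s) without exons skipped", sum(empty))
    exl <- exl[!empty]
  }
  gene_models(exl, genome)
}

#' Write gene models as GFF3
#' @param models A `gene_models`.
#' @param path Output path.
#' @export
write_gff3_genes <- function(models, path) {
  rows <- character(0)
  for (i in seq_along(models$gene_id)) {
    id <- models$gene_id[i]
    ex <- models$exons[[i]]
    chr <- as.character(GenomicRanges::seqnames(ex)[1])
    s <- models$strand[[i]]
    g0 <- min(GenomicRanges::start(ex)); g1 <- max(GenomicRanges::end(ex))
    rows <- c(rows,
      sprintf("%s\twagoseq\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s", chr, g0, g1, s, id),
      sprintf("%s\twagoseq\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene:%s",
              chr, g0, g1, s, id, id),
      sprintf("%s\twagoseq\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              chr, GenomicRanges::start(ex), GenomicRanges::end(ex), s,
              id, seq_along(ex), id))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Mature transcript sequences
#'
#' Concatenates exon sequence in the 5' to 3' orientation of the mRNA
#' (reverse-complemented for minus-strand genes).
#'
#' @param models A `gene_models`.
#' @param genome A [genome_index].
#' @return A named [Biostrings::DNAStringSet], one entry per gene.
#' @export
transcript_seqs <- function(models, genome) {
  ids <- models$gene_id
  if (length(ids) == 0) return(Biostrings::DNAStringSet())
  unl <- unlist(models$exons, use.names = FALSE)
  gene <- rep(ids, S4Vectors::elementNROWS(models$exons))
  chr <- as.character(GenomicRanges::seqnames(unl))
  pieces <- character(length(unl))
  for (ch in unique(chr)) {
    sel <- chr == ch
    pieces[sel] <- as.character(Biostrings::extractAt(
      genome$seqs[[ch]],
      IRanges::IRanges(GenomicRanges::start(unl)[sel],
                       GenomicRanges::end(unl)[sel])))
  }
  joined <- vapply(split(pieces, factor(gene, levels = ids)),
                   paste, "", collapse = "")
  minus <- models$strand == "-"
  joined[minus] <- revcomp(joined[minus])
  Biostrings::DNAStringSet(setNames(joined, ids))
}

#' All intron ranges across a gene-model set
#' @param models A `gene_models`.
#' @return A `GRanges` of every intron, with a `gene` metadata column.
#' @export
intron_ranges <- function(models) {
  unl <- unlist(models$introns, use.names = TRUE)
  if (length(unl)) S4Vectors::mcols(unl)$gene <- names(unl)
  unname(unl)
}

#' All exon ranges across a gene-model set
#' @param models A `gene_models`.
#' @return A `GRanges` of every exon, with a `gene` metadata column.
#' @export
exon_ranges <- function(models) {
  unl <- unlist(models$exons, use.names = TRUE)
  if (length(unl)) S4Vectors::mcols(unl)$gene <- names(unl)
  unname(unl)
}
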