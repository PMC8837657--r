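#' Annotation bundle
#'
#' Stranded interval sets for the annotation classes the classifier and the
#' WAGO-repeat caller consume, plus gene models and the mitochondrial contig
#' set. Classes may overlap one another; the classifier resolves conflicts
#' by priority.
#'
#' @param rRNA,tRNA,miRNA,repeats `GRanges` of the respective loci
#'   (`repeats` is the repeat catalog, not called WAGO-repeats).
#' @param models A [gene_models] object (may be empty).
#' @param genome A [genome_index]; intervals are validated against it and
#'   its `mito_contigs` are carried along.
#' @return An object of class `annotation_bundle`.
#' @export
annotation_bundle <- function(genome, models,
                              rRNA = GenomicRanges::GRanges(),
                              tRNA = GenomicRanges::GRanges(),
                              miRNA = GenomicRanges::GRanges(),
                              repeats = GenomicRanges::GRanges()) {
  classes <- list(rRNA = rRNA, tRNA = tRNA, miRNA = miRNA, repeats = repeats)
  for (cl in names(classes)) {
    gr <- classes[[cl]]
    if (length(gr) == 0) next
    chr <- as.character(GenomicRanges::seqnames(gr))
    unknown <- setdiff(chr, names(genome$lengths))
    if (length(unknown)) stopf("%s interval on unknown contig %s", cl, unknown[1])
    if (any(GenomicRanges::end(gr) > genome$lengths[chr]) ||
        any(GenomicRanges::start(gr) < 1))
      stopf("%s interval outside contig bounds", cl)
  }
  structure(c(classes,
              list(models = models, mito_contigs = genome$mito_contigs)),
            class = "annotation_bundle")
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf(
    "annotation_bundle: %d rRNA, %d tRNA, %d miRNA, %d repeat loci, %d genes\n",
    length(x$rRNA), length(x$tRNA), length(x$miRNA), length(x$repeats),
    length(x$models$gene_id)))
  invisible(x)
}

#' Blacklist intervals for locus filtering
#'
#' The union of rRNA, tRNA and miRNA loci plus the full span of every
#' mitochondrial contig, per the locus-calling filter ("remove loci related
#' to rRNA, tRNAs, miRNAs or mitochondrial DNA").
#'
#' @param annotations An `annotation_bundle`.
#' @param genome A [genome_index] (supplies mito contig lengths).
#' @return An unstranded `GRanges`.
#' @export
blacklist_ranges <- function(annotations, genome) {
  grs <- list(GenomicRanges::granges(annotations$rRNA),
              GenomicRanges::granges(annotations$tRNA),
              GenomicRanges::granges(annotations$miRNA))
  mito <- annotations$mito_contigs
  if (length(mito)) {
    grs <- c(grs, list(GenomicRanges::GRanges(
      seqnames = mito,
      ranges = IRanges::IRanges(1, unname(genome$lengths[mito])))))
  }
  gr <- suppressWarnings(do.call(c, grs))
  GenomicRanges::strand(gr) <- "*"
  GenomicRanges::reduce(gr)
}
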