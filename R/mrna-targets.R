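#' Antisense small-RNA rpkm per gene
#'
#' Reads antisense to a mature transcript are counted per gene, with a
#' multimapping read's copy number split evenly across its antisense
#' transcript hits, and converted to rpkm using the mature transcript
#' length (kb) and the library's total mapped reads (millions).
#'
#' @param placements A [place_reads()] result (transcript hits required).
#' @param models The [gene_models] used to build the placement index.
#' @return Named numeric vector of antisense rpkm, one entry per gene.
#' @export
antisense_gene_rpkm <- function(placements, models) {
  if (placements$total_mapped == 0) stopf("library has no mapped reads")
  rpkm <- setNames(rep(0, length(models$gene_id)), models$gene_id)
  th <- placements$tx_hits
  th <- th[th$antisense, , drop = FALSE]
  if (nrow(th)) {
    w <- placements$counts[th$read] / placements$n_tx_antisense[th$read]
    mass <- tapply(w, th$gene, sum)
    rpkm[names(mass)] <- as.numeric(mass)
  }
  rpkm / (models$mature_length / 1e3 * placements$total_mapped / 1e6)
}

#' Antisense rpkm matrix over several libraries
#'
#' @param placements_list Named list of [place_reads()] results; names
#'   become the column (library) names.
#' @param models A [gene_models].
#' @return A genes x libraries numeric matrix.
#' @export
antisense_rpkm_matrix <- function(placements_list, models) {
  stopifnot(length(placements_list) >= 1)
  m <- vapply(placements_list, antisense_gene_rpkm,
              numeric(length(models$gene_id)), models = models)
  matrix(m, nrow = length(models$gene_id),
         dimnames = list(models$gene_id,
                         names(placements_list) %||%
                           seq_along(placements_list)))
}

#' High-confidence mRNA target calls
#'
#' A gene is a high-confidence target in a library when its antisense
#' small-RNA rpkm is strictly over the threshold (default 10, the
#' published rule; an rpkm of exactly 10 is not a target).
#'
#' @param rpkm_matrix Genes x libraries matrix from
#'   [antisense_rpkm_matrix()] (or a named vector for one library).
#' @param threshold rpkm cutoff (default 10, strict inequality).
#' @return A list with `per_library` (named list of gene-id character
#'   vectors) and `union` (genes targeted in at least one library).
#' @export
call_targets <- function(rpkm_matrix, threshold = 10) {
  if (is.null(dim(rpkm_matrix)))
    rpkm_matrix <- matrix(rpkm_matrix, ncol = 1,
                          dimnames = list(names(rpkm_matrix), "library"))
  per <- lapply(seq_len(ncol(rpkm_matrix)), function(j)
    rownames(rpkm_matrix)[rpkm_matrix[, j] > threshold])
  names(per) <- colnames(rpkm_matrix)
  list(per_library = per, union = unique(unlist(per, use.names = FALSE)))
}

#' Expression groups across germline stages
#'
#' Operationalizes the published grouping with its own background rule
#' (expressed = rpkm at or above `expressed_min`, default 5):
#' `constitutive` genes are expressed in every one of M1-M7;
#' `meiosis_specific` genes are expressed in at least one of M5-M7 and in
#' none of M1-M4; everything else is `other`.
#'
#' @param expr Genes x stages matrix of expression rpkm with columns
#'   including `M1`..`M7`.
#' @param expressed_min Background expression cutoff (default 5 rpkm).
#' @return Factor of group labels, named by gene.
#' @export
expression_groups <- function(expr, expressed_min = 5) {
  need <- paste0("M", 1:7)
  if (!all(need %in% colnames(expr)))
    stopf("missing stage columns: %s",
          paste(setdiff(need, colnames(expr)), collapse = ", "))
  on <- expr[, need, drop = FALSE] >= expressed_min
  constitutive <- rowSums(on) == 7L
  meiosis <- rowSums(on[, c("M5", "M6", "M7"), drop = FALSE]) >= 1L &
    rowSums(on[, c("M1", "M2", "M3", "M4"), drop = FALSE]) == 0L
  g <- ifelse(constitutive, "constitutive",
              ifelse(meiosis, "meiosis_specific", "other"))
  factor(setNames(g, rownames(expr)),
         levels = c("constitutive", "meiosis_specific", "other"))
}

#' Metagene profile of antisense read 5' ends
#'
#' Each antisense read contributes its 5'-end position, in mature-transcript
#' coordinates (5' to 3' of the mRNA), to one of `bins` equal-width bins.
#' The aggregate profile pools copy-number-weighted counts over the gene
#' set and normalizes to sum 1. The 5' bias ratio compares the first and
#' last quintile of bins; when the last quintile is empty the ratio is
#' reported as the `bias_cap` sentinel.
#'
#' Because the read is antisense, its 5' end pairs with the 3'-most
#' transcript position it covers.
#'
#' @param placements A [place_reads()] result.
#' @param models A [gene_models].
#' @param genes Gene ids to profile (default: all genes with mature length
#'   at least `bins`).
#' @param bins Number of bins B (default 50).
#' @param bias_cap Sentinel for an infinite bias ratio (default 100).
#' @return A list with `profile` (length-`bins` density), `bias`
#'   (first-quintile mass / last-quintile mass), `n_reads` (weighted reads
#'   used) and `genes`.
#' @export
metagene <- function(placements, models, genes = NULL, bins = 50,
                     bias_cap = 100) {
  if (is.null(genes))
    genes <- models$gene_id[models$mature_length >= bins]
  genes <- intersect(genes, models$gene_id)
  genes <- genes[models$mature_length[genes] >= bins]
  if (length(genes) == 0) stopf("empty gene set for metagene profile")
  th <- placements$tx_hits
  th <- th[th$antisense & th$gene %in% genes, , drop = FALSE]
  prof <- rep(0, bins)
  if (nrow(th)) {
    w <- placements$counts[th$read] / placements$n_tx_antisense[th$read]
    pos5 <- th$end                      # antisense: read 5' end = hit 3' end
    len <- models$mature_length[th$gene]
    bin <- pmin(bins, ceiling(pos5 / len * bins))
    mass <- tapply(w, factor(bin, levels = seq_len(bins)), sum)
    prof <- ifelse(is.na(mass), 0, as.numeric(mass))
  }
  n <- sum(prof)
  if (n > 0) prof <- prof / n
  q <- bins %/% 5L
  first <- sum(prof[seq_len(q)])
  last <- sum(prof[seq.int(bins - q + 1L, bins)])
  bias <- if (last == 0) {
    if (first == 0) NA_real_ else bias_cap
  } else min(first / last, bias_cap)
  list(profile = prof, bias = bias, n_reads = n, genes = genes)
}

#' Percentage of a universe covered by a target set
#'
#' `100 * |target intersect universe| / |universe|`; report with
#' `round()` to match the "~89%" style of summary statements.
#'
#' @param target,universe Character vectors of ids (universe non-empty).
#' @return Unrounded percentage.
#' @export
target_fraction <- function(target, universe) {
  if (length(universe) == 0) stopf("empty universe")
  100 * length(intersect(target, universe)) / length(unique(universe))
}
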