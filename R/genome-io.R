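#' Genome index
#'
#' Container for a genome: contig sequences, lengths, and the set of contigs
#' flagged as mitochondrial. Mitochondrial contigs are excluded from mean
#' genome coverage and blacklist WAGO-repeat loci.
#'
#' @param seqs A named [Biostrings::DNAStringSet] of contig sequences.
#' @param mito_contigs Character vector of mitochondrial contig names
#'   (must be a subset of `names(seqs)`).
#' @return An object of class `genome_index` with elements `seqs`, `lengths`
#'   (named integer) and `mito_contigs`.
#' @export
genome_index <- function(seqs, mito_contigs = character()) {
  if (!is(seqs, "DNAStringSet")) stopf("`seqs` must be a DNAStringSet")
  nm <- names(seqs)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) stopf("all contigs must be named")
  if (anyDuplicated(nm)) stopf("duplicate contig name: %s", nm[duplicated(nm)][1])
  if (any(Biostrings::width(seqs) == 0)) stopf("contig of length 0: %s",
                                              nm[Biostrings::width(seqs) == 0][1])
  missing <- setdiff(mito_contigs, nm)
  if (length(missing)) stopf("mito contig not in genome: %s", missing[1])
  structure(
    list(seqs = seqs,
         lengths = setNames(Biostrings::width(seqs), nm),
         mito_contigs = as.character(mito_contigs)),
    class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("genome_index: %d contigs, %s bp total (%d mitochondrial)\n",
              length(x$lengths), format(sum(as.numeric(x$lengths)), big.mark = ","),
              length(x$mito_contigs)))
  invisible(x)
}

#' Seqinfo for a genome index
#' @param genome A `genome_index`.
#' @return A [GenomeInfoDb::Seqinfo] with the contig lengths.
#' @export
genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome$lengths),
                        seqlengths = unname(genome$lengths))
}

#' Read a genome FASTA
#'
#' Loads all contigs, upper-cases the sequence, and rejects duplicate contig
#' names. The contig name is the first whitespace-delimited token of the
#' FASTA header.
#'
#' @param path Path to a FASTA file.
#' @param mito_contigs Contig names to flag as mitochondrial.
#' @return A [genome_index].
#' @export
read_fasta_genome <- function(path, mito_contigs = character()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stopf("malformed FASTA '%s': %s",
                                             path, conditionMessage(e)))
  if (length(seqs) == 0) stopf("no sequences in FASTA: %s", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  genome_index(seqs, mito_contigs)
}

#' Write a genome index to FASTA
#' @param genome A `genome_index`.
#' @param path Output path.
#' @export
write_fasta_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}
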