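#' Small-RNA library
#'
#' A collapsed (non-redundant) small-RNA library: one row per distinct
#' sequence with its copy number. The classification window is 18-30 nt;
#' reads outside it are retained but flagged.
#'
#' @param seqs Character vector of read sequences over A/C/G/T.
#' @param counts Positive integer copy numbers, recycled-length 1 allowed.
#' @param id Library identifier.
#' @param stage Stage label (e.g. "M1".."M8", "ovary", "4cell").
#' @param argonaute Argonaute/archetype label, or "input".
#' @return An object of class `srna_library`: a list with `reads` (a
#'   data.frame of `seq`, `count`, `length`, `first_nt`, `in_range`), the
#'   labels above, and `total_mapped` (NA until placement).
#' @export
srna_library <- function(seqs, counts = 1L, id = "lib", stage = NA_character_,
                         argonaute = NA_character_) {
  counts <- rep_len(as.integer(counts), length(seqs))
  if (length(seqs) && anyDuplicated(seqs)) {
    counts <- as.integer(rowsum(counts, seqs)[, 1])
    seqs <- sort(unique(seqs))
    ## rowsum sorts groups alphabetically; realign
  }
  if (any(counts < 1)) stopf("counts must be >= 1")
  if (length(seqs) && any(grepl("[^ACGT]", seqs))) stopf("non-ACGT sequence in library")
  len <- nchar(seqs)
  structure(
    list(reads = data.frame(seq = as.character(seqs), count = counts,
                            length = len, first_nt = first_nt(seqs),
                            in_range = len >= 18L & len <= 30L,
                            stringsAsFactors = FALSE),
         id = id, stage = stage, argonaute = argonaute,
         total_mapped = NA_real_, dropped = 0L),
    class = "srna_library")
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("srna_library '%s' (stage %s, %s): %d distinct reads, %s copies\n",
              x$id, x$stage, x$argonaute, nrow(x$reads),
              format(sum(x$reads$count), big.mark = ",")))
  invisible(x)
}

#' Total copies in a library
#' @param lib An `srna_library`.
#' @export
library_size <- function(lib) sum(lib$reads$count)

#' Read and collapse a small-RNA library
#'
#' Reads a FASTA or FASTQ file of adapter-trimmed small-RNA reads, drops
#' reads containing characters outside A/C/G/T (including N, which exact
#' placement cannot use), and collapses identical sequences, summing
#' copy numbers. Pre-collapsed FASTA headers may carry counts in the
#' `"<id>_x<count>"` dialect; a header without the suffix counts as 1.
#'
#' @param path FASTA/FASTQ file (`.fq`/`.fastq` extensions parsed as FASTQ).
#' @param id,stage,argonaute Library labels (default `id` = file basename).
#' @return An [srna_library]; the number of dropped reads is stored in the
#'   `dropped` element.
#' @export
read_small_rna_library <- function(path, id = NULL, stage = NA_character_,
                                   argonaute = NA_character_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path)
  ss <- Biostrings::readDNAStringSet(path, format = if (fastq) "fastq" else "fasta")
  seqs <- toupper(as.character(ss))
  headers <- sub("\\s.*$", "", names(ss))
  counts <- rep(1L, length(seqs))
  has <- grepl("_x\\d+$", headers)
  counts[has] <- as.integer(sub("^.*_x(\\d+)$", "\\1", headers[has]))
  ok <- !grepl("[^ACGT]", seqs)
  lib <- srna_library(seqs[ok], counts[ok],
                      id = id %||% sub("\\.[^.]*$", "", basename(path)),
                      stage = stage, argonaute = argonaute)
  lib$dropped <- sum(counts[!ok])
  lib
}

#' Write a library as collapsed FASTA
#'
#' Headers use the `"<id>_x<count>"` count dialect read back by
#' [read_small_rna_library()].
#' @param lib An `srna_library`.
#' @param path Output path.
#' @export
write_collapsed_fasta <- function(lib, path) {
  ss <- Biostrings::DNAStringSet(lib$reads$seq)
  names(ss) <- sprintf("%s_r%06d_x%d", lib$id, seq_len(nrow(lib$reads)),
                       lib$reads$count)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a library as FASTQ (one record per copy, constant qualities)
#' @param lib An `srna_library`.
#' @param path Output path.
#' @export
write_fastq <- function(lib, path) {
  idx <- rep(seq_len(nrow(lib$reads)), lib$reads$count)
  seqs <- lib$reads$seq[idx]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", lib$id, "_", seq_along(idx), "\n", seqs, "\n+\n",
                    vapply(nchar(seqs), function(n)
                      paste(rep("I", n), collapse = ""), "")),
             con)
  invisible(path)
}
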