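#' Read a BED3/BED6 file into a GRanges
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' convention of [GenomicRanges::GRanges] at this boundary. Strand is `*`
#' when the file has fewer than six columns. Records are returned sorted by
#' contig then start.
#'
#' @param path Path to a BED file (3 or 6+ tab-separated columns).
#' @param class_label Optional feature-class label stored in the `class`
#'   metadata column (e.g. `"rRNA"`).
#' @return A `GRanges`, with `name` and `class` metadata columns.
#' @export
read_bed <- function(path, class_label = NA_character_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(GenomicRanges::GRanges(name = character(), class = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3)) stopf("BED line %d: fewer than 3 columns", which(ncols < 3)[1])
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) stopf("BED line %d: non-numeric coordinates", bad[1])
  bad <- which(start0 < 0)
  if (length(bad)) stopf("BED line %d: negative start", bad[1])
  bad <- which(start0 >= end0)
  if (length(bad)) stopf("BED line %d: start >= end", bad[1])
  name <- ifelse(ncols >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  strand <- ifelse(ncols >= 6, vapply(fields, function(f) f[min(6L, length(f))], ""),
                   "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand,
    name = name,
    class = class_label)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges as BED6
#'
#' Inverse of [read_bed()]: 1-based closed ranges are written 0-based
#' half-open, sorted by contig then start.
#'
#' @param gr A `GRanges`. A `name` metadata column is used if present; a
#'   `score` column likewise (0 otherwise).
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  mc <- S4Vectors::mcols(gr)
  name <- if ("name" %in% names(mc)) as.character(mc$name) else NA_character_
  name[is.na(name)] <- "."
  score <- if ("score" %in% names(mc)) mc$score else 0
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = format(GenomicRanges::start(gr) - 1, scientific = FALSE, trim = TRUE),
    end = format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE),
    name = name, score = score, strand = strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
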