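#' Row-wise standard Z-scores
#'
#' Standardizes each feature (row) across libraries using the population
#' standard deviation (divisor n). Constant rows are set to all zeros and
#' flagged in the `constant_rows` attribute.
#'
#' @param mat Features x libraries numeric matrix (at least two columns).
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  if (is.null(dim(mat)) || ncol(mat) < 2)
    stopf("Z-scores need at least two libraries (columns)")
  mu <- rowMeans(mat)
  sd_pop <- sqrt(rowMeans((mat - mu)^2))
  z <- (mat - mu) / ifelse(sd_pop == 0, 1, sd_pop)
  z[sd_pop == 0, ] <- 0
  attr(z, "constant_rows") <- which(sd_pop == 0)
  z
}

#' PCA of small-RNA libraries
#'
#' Deterministic transform: values are log2(rpkm + 1); the `n_top` most
#' variable features are selected; features are centered; principal
#' components come from singular value decomposition. Component signs are
#' fixed by making the largest-magnitude loading of each component
#' positive, so results are reproducible bit for bit.
#'
#' @param mat Features x libraries rpkm matrix (at least 3 libraries).
#' @param n_top Number of most-variable features kept (default 500).
#' @param n_components Components to return (default 2).
#' @return A list with `coords` (libraries x components), `var_explained`
#'   (percentage per component, all components, summing to 100),
#'   `loadings`, and `features` (the ids kept).
#' @export
pca_libraries <- function(mat, n_top = 500, n_components = 2) {
  if (ncol(mat) < 3) stopf("PCA needs at least 3 libraries")
  x <- log2(mat + 1)
  v <- apply(x, 1, var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(x)))]
  xs <- x[keep, , drop = FALSE]
  pc <- prcomp(t(xs), center = TRUE, scale. = FALSE)
  if (n_components > length(pc$sdev))
    stopf("n_components exceeds the number of components (%d)", length(pc$sdev))
  for (j in seq_along(pc$sdev)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, seq_len(n_components), drop = FALSE],
       var_explained = ve,
       loadings = pc$rotation,
       features = rownames(mat)[keep] %||% keep)
}

#' Venn region cardinalities for 2 or 3 sets
#'
#' @param sets Named list of 2 or 3 vectors of ids.
#' @return Named integer vector of region counts: for two sets A and B,
#'   `A_only`, `B_only`, `A.B`; for three, the seven regions. Counts sum to
#'   the size of the union.
#' @export
venn_counts <- function(sets) {
  if (!length(sets) %in% c(2L, 3L))
    stopf("venn_counts handles 2 or 3 sets (got %d); use a pairwise matrix",
          length(sets))
  nm <- names(sets) %||% LETTERS[seq_along(sets)]
  sets <- lapply(sets, unique)
  univ <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  memb <- matrix(memb, ncol = length(sets))
  key <- apply(memb, 1, function(r) paste(nm[r], collapse = "."))
  if (length(sets) == 2L) {
    regions <- c(paste0(nm[1], "_only"), paste0(nm[2], "_only"),
                 paste(nm, collapse = "."))
    keys <- c(nm[1], nm[2], paste(nm, collapse = "."))
  } else {
    keys <- c(nm[1], nm[2], nm[3],
              paste(nm[c(1, 2)], collapse = "."),
              paste(nm[c(1, 3)], collapse = "."),
              paste(nm[c(2, 3)], collapse = "."),
              paste(nm, collapse = "."))
    regions <- c(paste0(nm, "_only"), keys[4:7])
  }
  counts <- vapply(keys, function(k) sum(key == k), 0L)
  setNames(as.integer(counts), regions)
}

#' Repeat-versus-mRNA target plasticity across a stage series
#'
#' Summarizes, per stage, the fraction of classified read mass on
#' WAGO-repeats versus antisense mRNA (remainder = other categories), and
#' reports the switch stage: the first stage at which the antisense-mRNA
#' fraction exceeds the WAGO-repeat fraction (NA when it never does).
#'
#' @param profiles Named list of [category_profile()] data.frames, one per
#'   stage, in stage order (names are the stage labels).
#' @return A data.frame with columns `stage`, `wago_repeats`,
#'   `antisense_mrna`, `other`, and attribute `switch_stage`.
#' @export
plasticity_summary <- function(profiles) {
  if (length(profiles) == 0) stopf("no stage profiles supplied")
  stages <- names(profiles) %||% paste0("S", seq_along(profiles))
  take <- function(p, cat) p$fraction[p$category == cat]
  rep_f <- vapply(profiles, take, 0, cat = "WAGO_repeats")
  mrna_f <- vapply(profiles, take, 0, cat = "antisense_mRNA")
  out <- data.frame(stage = stages, wago_repeats = rep_f,
                    antisense_mrna = mrna_f,
                    other = 1 - rep_f - mrna_f, row.names = NULL)
  sw <- which(mrna_f > rep_f)
  attr(out, "switch_stage") <- if (length(sw)) stages[sw[1]] else NA_character_
  out
}
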