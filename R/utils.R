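#' @importFrom methods is
#' @importFrom stats prcomp rbinom rlnorm rmultinom rnorm runif setNames var
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Deterministic small integer offset for deriving per-library seeds (< 2^31).
seed_offset <- function(label) {
  sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 10000L
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

first_nt <- function(seqs) {
  nt <- substr(seqs, 1L, 1L)
  nt[nt == "T"] <- "U"
  factor(nt, levels = c("A", "C", "G", "U"))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
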