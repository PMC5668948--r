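#' @import data.table
#' @importFrom stats median rnorm runif rbinom setNames rpois quantile binom.test mad
#' @importFrom utils head tail write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## run `expr` under a locally-seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## derive a child seed from a parent seed and a stream label; stays < 2^31
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

## smallest value attaining the maximum count (modal position, ties -> smaller)
modal_min <- function(x) {
  if (length(x) == 0L) return(NA_integer_)
  tb <- table(x)
  as.integer(names(tb)[which(tb == max(tb))[1L]])  # names(table) sorted ascending
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

## positions (0-based) of the C in CpG dinucleotides, plus the G position:
## a mutation at either base of a CpG is treated as CpG-associated
cpg_positions <- function(seq) {
  hits <- gregexpr("CG", seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  sort(unique(c(hits - 1L, hits)))  # 0-based C and G positions
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
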