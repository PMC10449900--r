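#' @importFrom stats rbinom rpois rlnorm rnorm runif median sd setNames
#' @importFrom utils head tail write.table read.table
#' @importFrom data.table data.table as.data.table setDT setorder rbindlist :=
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible child seed for a pipeline stage
#'
#' All stochastic stages draw from their own child seed derived from the
#' master seed, so a stage can be re-run in isolation and still reproduce
#' the outputs of a full run.
#'
#' @param seed master seed (integer).
#' @param stage character stage label.
#' @param index optional integer index (e.g. cell number).
#' @return an integer seed in `[0, 2^31)`.
#' @export
child_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 101 + index * 13) %% 2147483629)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a random DNA sequence
#'
#' @param n length in bases.
#' @return a single character string over A/C/G/T.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## 0-based half-open interval helpers -------------------------------------

iv_len <- function(start, end) end - start

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
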