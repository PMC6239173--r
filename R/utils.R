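## Internal helpers: seeded RNG scoping and sequence utilities.

# Evaluate `expr` under a private, reproducible RNG state. The caller's
# .Random.seed is restored afterwards, so simulation calls never perturb the
# session RNG ("all randomness from one seeded generator per call").
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  expr
}

# Derive a stream-specific child seed so that independent stages given the
# same user seed do not share a random stream. Kept below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream) %% 2147483647
}

#' Reverse-complement DNA sequences
#'
#' Vectorised reverse complement over character vectors of uppercase
#' ACGT/N sequences.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  cpp_revcomp(x)
}

# random uppercase DNA of given lengths (vectorised)
random_dna <- function(lengths) {
  vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
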