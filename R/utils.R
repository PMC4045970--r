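MISSING_CALL <- "--"

#' Deterministic child seed
#'
#' Derives a reproducible 32-bit seed for a named sub-task from a master
#' seed, so that independent stages of a simulation do not share streams.
#'
#' @param seed integer master seed.
#' @param what character tag naming the sub-task.
#' @return An integer seed below 2^31.
#' @keywords internal
child_seed <- function(seed, what) {
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_radmap <- function(...) stop(sprintf(...), call. = FALSE)

#' Random DNA sequence
#' @param n length in bases.
#' @return A single character string over {A,C,G,T}.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
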