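#' @importFrom stats rbinom rpois rnorm runif setNames sd qnbinom dnbinom
#' @importFrom utils head tail write.table read.table
NULL

BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide string to DNA alphabet
#'
#' Uppercases and converts U to T so that RNA- and DNA-encoded sequences
#' (e.g. miRBase matures vs genomic tags) compare equal.
#'
#' @param x character vector of sequences.
#' @return character vector over A/C/G/T (plus any ambiguity codes as-is).
#' @export
norm_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Normalize a nucleotide string to RNA alphabet (T -> U)
#' @param x character vector of sequences.
#' @return character vector over A/C/G/U.
#' @export
norm_rna <- function(x) {
  chartr("T", "U", toupper(x))
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(norm_dna(x))))
}

#' GC fraction of a sequence
#' @param x character vector of sequences.
#' @return numeric vector of G+C fractions in \[0, 1\].
#' @export
gc_fraction <- function(x) {
  x <- norm_dna(x)
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  ifelse(n > 0, gc / n, NA_real_)
}

#' A+U (A+T) fraction of a sequence
#' @param x character vector of sequences.
#' @return numeric vector of A+U fractions in \[0, 1\].
#' @export
au_fraction <- function(x) {
  x <- norm_dna(x)
  n <- nchar(x)
  at <- nchar(gsub("[^AT]", "", x))
  ifelse(n > 0, at / n, NA_real_)
}

# Random DNA at a target GC fraction; uses the current RNG stream.
random_dna <- function(n, gc = 0.5, length = NULL) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  if (is.null(length)) {
    paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
  } else {
    vapply(seq_len(n), function(i) {
      paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  }
}

# substr() for a vector of (start, end) on one long string
substr_vec <- function(x, start, end) {
  substring(x, start, end)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
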