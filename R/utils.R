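## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Convert between GFF-style and internal coordinates
#'
#' The package interface speaks GFF3 1-based inclusive coordinates; internal
#' region arithmetic is 0-based half-open.  All conversion funnels through
#' this one pair of functions.
#'
#' @param start,end 1-based inclusive coordinates.
#' @return For `to_zero_based()`, a list with `start` (0-based) and `end`
#'   (exclusive); `from_zero_based()` inverts it.
#' @keywords internal
to_zero_based <- function(start, end) list(start = start - 1L, end = end)

#' @rdname to_zero_based
#' @param zstart,zend 0-based half-open coordinates.
#' @keywords internal
from_zero_based <- function(zstart, zend) list(start = zstart + 1L, end = zend)

## Split a DNA string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

chars_seq <- function(x) paste(x, collapse = "")

## Reverse complement for plain character strings (delegates to Biostrings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Extract substring on a circular sequence, 1-based inclusive, possibly
## wrapping the origin (end < start).
circular_substr <- function(seq, start, end, circular = TRUE) {
  n <- nchar(seq)
  if (start < 1L || start > n || end < 1L || end > n)
    stop("coordinates [", start, ", ", end, "] outside sequence of length ", n)
  if (end >= start) return(substr(seq, start, end))
  if (!circular)
    stop("end < start (", start, "..", end, ") on a non-circular sequence")
  paste0(substr(seq, start, n), substr(seq, 1L, end))
}

## Random DNA of length n at a GC target, from an already-seeded RNG.
random_dna <- function(n, gc = 0.333) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars_seq(sample(DNA_BASES, n, replace = TRUE, prob = p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
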