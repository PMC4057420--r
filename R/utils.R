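#' @keywords internal
"_PACKAGE"

#' @importFrom methods is
#' @importFrom stats median density bw.nrd0 rbinom rgeom runif setNames aggregate
#' @importFrom utils read.delim write.table head
#' @importFrom graphics plot
NULL

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper used throughout the junction
#' bookkeeping (P-nucleotide comparisons, minus-strand motif matches).
#'
#' @param x character vector of DNA strings over A, C, G, T, N.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("TACTAC")  # "GTAGTA"
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(s)
    paste(rev(COMPLEMENT[strsplit(toupper(s), "", fixed = TRUE)[[1]]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Percent rounding, half away from zero (matches integer reporting in
## repertoire tables; base round() is banker's rounding).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## 0-based half-open span helper: all coordinates exposed by this package
## follow this convention.
span0 <- function(start0, end0) {
  stopifnot(all(end0 >= start0))
  list(start = start0, end = end0)
}

chartokens <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
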