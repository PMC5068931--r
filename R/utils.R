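# Shared numeric and interval helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed tables in this field
#' conventionally round half up. Used wherever a percentage is reported.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run code with a private RNG stream: seeds explicitly, restores global state.
with_rng <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Total length of the union of 0-based half-open intervals [start, end).
# Thin wrapper over IRanges::reduce on the 1-based closed representation.
interval_union_length <- function(start0, end0) {
  stopifnot(length(start0) == length(end0))
  if (length(start0) == 0) return(0L)
  r <- IRanges::reduce(IRanges::IRanges(start = start0 + 1L, end = end0))
  sum(IRanges::width(r))
}

# Reverse complement of an ACGTN character vector of sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
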