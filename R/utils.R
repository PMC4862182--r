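#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements (uppercase).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

#' Find homopolymer runs in a sequence
#'
#' Returns all maximal runs of `base` with length >= k as a data.frame of
#' 0-based half-open [start, end) offsets within the string.
#'
#' @param seq single DNA string.
#' @param base single character, e.g. "A".
#' @param k minimum run length.
#' @return data.frame with columns start, end, length.
#' @export
homopolymer_runs <- function(seq, base, k = 6L) {
  stopifnot(length(seq) == 1L, nchar(base) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  r <- rle(chars == toupper(base))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= k
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable 32-bit sub-seed derived from a master seed and a stream label
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) * 7919 + sum(utf8ToInt(as.character(stream)))) %% 2147483647
  as.integer(max(1, s))
}
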