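#' Amino acid alphabets
#'
#' `motifAlphabet()` returns an ordered character vector of unique one-letter
#' symbols used as the residue alphabet for motif classes. The default is the
#' canonical 20 proteinogenic amino acids. Sizes above 20 model chemically
#' expanded alphabets (selenocysteine plus effective post-translational
#' modifications, see [expandedAlphabetSize()]): position 21 is `"U"`
#' (selenocysteine) and further positions use lower-case placeholder symbols,
#' since the combinatorial theory only depends on alphabet size, not on symbol
#' identity. Sizes below 20 (useful for exhaustive tests) take the first
#' `size` canonical symbols.
#'
#' @param size Integer alphabet size, `>= 2`.
#' @return Character vector of `size` unique single-character symbols.
#' @examples
#' motifAlphabet()      # the 20 canonical amino acids
#' motifAlphabet(4)     # A C D E, for small exhaustive examples
#' length(motifAlphabet(33))
#' @export
motifAlphabet <- function(size = 20) {
  size <- .checkAlphabetSize(size)
  pool <- c(AA_CANONICAL, "U", letters)
  if (size > length(pool))
    stop("alphabet sizes above ", length(pool), " are not supported")
  pool[seq_len(size)]
}

#' @rdname motifAlphabet
#' @format `AA_CANONICAL` is the canonical 20-letter amino acid alphabet in
#'   alphabetical order.
#' @export
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.checkAlphabet <- function(alphabet) {
  if (!is.character(alphabet) || length(alphabet) < 2L ||
      anyDuplicated(alphabet) || any(nchar(alphabet) != 1L))
    stop("'alphabet' must be >= 2 unique single-character symbols")
  alphabet
}
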