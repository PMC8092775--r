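#' @include AllClasses.R
NULL

#' Number of distinct instances of a motif class or structure
#'
#' The number of distinct sequences matching a motif class equals the product
#' of the allowed-set sizes over its positions, \eqn{\prod_i e_i}. For the
#' structure (2,20,1,20,2) this is \eqn{2 \cdot 20 \cdot 1 \cdot 20 \cdot 2 =
#' 1600}.
#'
#' @param x A [MotifClass], or an integer vector giving a motif structure.
#' @return Numeric count (can exceed integer range for long motifs).
#' @examples
#' countInstances(c(2, 20, 1, 20, 2))   # 1600
#' countInstances(MotifClass("[LI].C.[DE]", "LIG_Rb"))
#' @export
countInstances <- function(x) {
  e <- if (is(x, "MotifClass")) motifStructure(x) else {
    e <- as.integer(x)
    if (length(e) < 1L || anyNA(e) || any(e < 1L))
      stop("'x' must be a MotifClass or a vector of positive set sizes")
    e
  }
  prod(as.numeric(e))
}

#' Does a sequence match a motif class?
#'
#' A sequence \eqn{(a_1,\dots,a_n)} is an instance of the class
#' \eqn{(A_1,\dots,A_n)} iff \eqn{a_i \in A_i} at every position. The
#' sequence must have the same length as the motif.
#'
#' @param sequence Character scalar (a residue string) or character vector of
#'   single symbols.
#' @param motif A [MotifClass].
#' @return `TRUE` or `FALSE`.
#' @examples
#' m <- MotifClass("[LI].C.[DE]", "LIG_Rb")
#' isInstance("IACDD", m)   # TRUE
#' isInstance("IACDP", m)   # FALSE
#' @export
isInstance <- function(sequence, motif) {
  stopifnot(is(motif, "MotifClass"))
  if (length(sequence) == 1L && nchar(sequence) != 1L)
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(sequence) != motifLength(motif))
    stop("sequence length ", length(sequence),
         " does not match motif length ", motifLength(motif))
  all(mapply(function(a, set) a %in% set, sequence, positions(motif)))
}
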