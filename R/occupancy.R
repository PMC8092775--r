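#' @include combinatorics.R
NULL

#' Sequence-space occupancy of motif classes
#'
#' `classOccupancy()` is the fraction of all \eqn{A^n} length-\eqn{n}
#' sequences that are instances of a single class of structure \eqn{e}:
#' \eqn{\prod_i e_i / A^n}. For (2,20,1,20,2) over 20 amino acids this is
#' \eqn{1600 / 20^5 = 0.0005}.
#'
#' `potentialOccupancy()` is the fraction occupied if all potential classes
#' of that structure came into existence at specificity level \eqn{k \ge 1}:
#' \deqn{\mathrm{PotentialOccupancy}(e, k) = \prod_i (e_i/A) \cdot |M(k)|,}
#' with the *unfloored* pigeonhole bound for \eqn{1 \le k < n} and the exact
#' \eqn{|M(n)|} at \eqn{k = n}. For \eqn{1 \le k < n} the per-class factor
#' cancels the retained bound factors exactly, so the function evaluates the
#' algebraically simplified product of the \eqn{k - 1} smallest \eqn{e_i/A};
#' in particular the value at \eqn{k = 1} is exactly 1 (every sequence
#' belongs to a potential class) and at \eqn{k = 2} it is
#' \eqn{\min_i e_i / A}. At \eqn{k = 0} instances may belong to several
#' classes at once and no formula is available; the function errors.
#'
#' @inheritParams potentialClasses
#' @return A real number; `classOccupancy()` in \eqn{(0, 1]}.
#' @examples
#' classOccupancy(c(2, 20, 1, 20, 2))           # 0.0005
#' potentialOccupancy(c(2, 20, 1, 20, 2), k = 1) # exactly 1
#' potentialOccupancy(c(2, 20, 1, 20, 2), k = 2) # 0.05
#' @export
classOccupancy <- function(structure, alphabetSize = 20) {
  A <- .checkAlphabetSize(alphabetSize)
  e <- .checkStructure(structure, A)
  prod(e / A)
}

#' @rdname classOccupancy
#' @export
potentialOccupancy <- function(structure, alphabetSize = 20, k) {
  A <- .checkAlphabetSize(alphabetSize)
  e <- .checkStructure(structure, A)
  n <- length(e)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k > n)
    stop("'k' must be a single integer in 1..n = ", n)
  if (k < 1L)
    stop("potential occupancy is undefined at k = 0: instances may belong ",
         "to several classes at once and no closed form is available")
  # k = 1 always uses the unfloored bound, so the telescoping identity gives
  # exactly 1 even for single-position structures (where k = 1 = n)
  if (k == 1L) return(1)
  if (k == n) return(prod(e / A) * mnExact(e, A))
  # algebraic cancellation of prod(e_i/A) against the unfloored upper bound:
  # only the k-1 smallest set sizes survive
  es <- sort(e, decreasing = TRUE)
  dropped <- if (k > 1L) es[(n - k + 2L):n] else numeric(0)
  prod(dropped / A)
}
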