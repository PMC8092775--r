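#' @include AllClasses.R
NULL

#' Bounds on the maximal number of k-discriminating motif classes
#'
#' For a fixed structure \eqn{e = (e_1,\dots,e_n)} and alphabet size
#' \eqn{A}, a family of motif classes is *k-discriminating* when every pair
#' of classes has at least \eqn{k} coordinates with disjoint allowed sets.
#' \eqn{|M(k)|} denotes the maximal size of such a family. The package
#' implements the closed-form bounds:
#' \describe{
#'   \item{`m0Upper()`}{\eqn{|M(0)| \le \prod_i \binom{A-1}{e_i-1}}, the
#'     per-position Erdős–Ko–Rado bound on pairwise-intersecting families.
#'     The formula is evaluated as stated even at positions with
#'     \eqn{2e_i > A}, where the Erdős–Ko–Rado hypothesis fails (a warning is
#'     emitted; such factors contribute their literal binomial value, e.g.
#'     \eqn{\binom{19}{19} = 1} for \eqn{e_i = 20}).}
#'   \item{`m1Lower()`}{the constructive lower bound
#'     \eqn{|M(1)| \ge \prod_i \lfloor A/e_i \rfloor}, realised by
#'     [buildDiscriminatingSet()].}
#'   \item{`mkUpper()`}{the pigeonhole upper bound
#'     \eqn{|M(k)| \le \prod_{i \le n-(k-1)} A/e_i} for \eqn{1 \le k \le n},
#'     with the \eqn{e_i} sorted in decreasing order before truncation so the
#'     bound is sharpest; returned unfloored.}
#'   \item{`mnExact()`}{the exact value at full discrimination,
#'     \eqn{|M(n)| = \min_i \lfloor A/e_i \rfloor}.}
#'   \item{`potentialClasses()`}{the reported number of potential classes:
#'     `m0Upper` at \eqn{k = 0}, `floor(mkUpper)` for \eqn{1 \le k < n}, and
#'     `mnExact` at \eqn{k = n}. The floor is applied once to the final
#'     product, never per factor (per-factor flooring belongs to the lower
#'     bound only).}
#' }
#' All bounds are invariant under reordering of the structure.
#'
#' @param structure Integer vector of allowed-set sizes
#'   \eqn{(e_1,\dots,e_n)}, each in `1..alphabetSize`.
#' @param alphabetSize Alphabet size \eqn{A} (default 20).
#' @param k Required number of motif-discriminating positions,
#'   `0 <= k <= length(structure)`.
#' @return `mkUpper()` a real value; the others integers (as numerics).
#' @examples
#' e <- c(2, 20, 1, 20, 2)
#' sapply(0:5, function(k) potentialClasses(e, 20, k)) # 361 2000 100 10 1 1
#' m1Lower(e, 33)                                # 8448
#' potentialClasses(c(8, 8, 8, 8), 20, 1)        # 39
#' @export
potentialClasses <- function(structure, alphabetSize = 20, k) {
  A <- .checkAlphabetSize(alphabetSize)
  e <- .checkStructure(structure, A)
  n <- length(e)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L || k > n)
    stop("'k' must be a single integer in 0..n = ", n)
  if (k == 0L) m0Upper(e, A)
  else if (k == n) mnExact(e, A)
  else .floorTol(mkUpper(e, A, k))
}

#' @rdname potentialClasses
#' @export
m0Upper <- function(structure, alphabetSize = 20) {
  A <- .checkAlphabetSize(alphabetSize)
  e <- .checkStructure(structure, A)
  if (any(2L * e > A))
    warning("Erdős–Ko–Rado hypothesis 2*e_i <= A fails at ",
            sum(2L * e > A), " position(s); the product is evaluated ",
            "literally there", call. = FALSE)
  prod(choose(A - 1, e - 1))
}

#' @rdname potentialClasses
#' @export
m1Lower <- function(structure, alphabetSize = 20) {
  A <- .checkAlphabetSize(alphabetSize)
  e <- .checkStructure(structure, A)
  prod(A %/% e)
}

#' @rdname potentialClasses
#' @export
mkUpper <- function(structure, alphabetSize = 20, k = 1) {
  A <- .checkAlphabetSize(alphabetSize)
  e <- .checkStructure(structure, A)
  n <- length(e)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n)
    stop("'k' must be a single integer in 1..n = ", n)
  es <- sort(e, decreasing = TRUE)
  prod(A / es[seq_len(n - (k - 1L))])
}

#' @rdname potentialClasses
#' @export
mnExact <- function(structure, alphabetSize = 20) {
  A <- .checkAlphabetSize(alphabetSize)
  e <- .checkStructure(structure, A)
  min(A %/% e)
}

#' Construct a 1-discriminating family of maximal constructive size
#'
#' Realises the constructive lower bound \eqn{\prod_i \lfloor A/e_i \rfloor}:
#' at each position \eqn{i} the alphabet is cut into
#' \eqn{p_i = \lfloor A/e_i \rfloor} pairwise-disjoint blocks of \eqn{e_i}
#' consecutive symbols, and the family is the Cartesian product of block
#' choices. Any two members differ in at least one coordinate, where their
#' blocks are disjoint, so every pair has at least one motif-discriminating
#' position.
#'
#' @inheritParams potentialClasses
#' @param alphabet Residue alphabet (its length is the alphabet size).
#' @return A [MotifDatabase] with exactly `m1Lower(structure, A)` classes.
#' @examples
#' fam <- buildDiscriminatingSet(c(7, 6))
#' length(fam)            # 6
#' mdp(fam[[1]], fam[[2]]) >= 1
#' @export
buildDiscriminatingSet <- function(structure, alphabet = motifAlphabet()) {
  .checkAlphabet(alphabet)
  A <- length(alphabet)
  e <- .checkStructure(structure, A)
  p <- A %/% e
  blocks <- lapply(seq_along(e), function(i)
    lapply(seq_len(p[i]), function(j)
      alphabet[((j - 1L) * e[i] + 1L):(j * e[i])]))
  grid <- expand.grid(lapply(p, seq_len), KEEP.OUT.ATTRS = FALSE)
  width <- nchar(as.character(nrow(grid)))
  classes <- lapply(seq_len(nrow(grid)), function(r) {
    pos <- lapply(seq_along(e), function(i) blocks[[i]][[grid[r, i]]])
    motifFromPositions(pos,
                       identifier = sprintf("D%0*d", width, r),
                       name = sprintf("block_family_%0*d", width, r),
                       alphabet = alphabet)
  })
  MotifDatabase(classes, alphabet = alphabet,
                provenance = list(
                  generator = "buildDiscriminatingSet",
                  structure = e, alphabetSize = A))
}

#' Exact maximal k-discriminating family size by exhaustive search
#'
#' Independent oracle for the closed-form bounds on tiny instances: all
#' \eqn{\prod_i \binom{A}{e_i}} candidate classes of the given structure are
#' enumerated, a compatibility graph is built (for \eqn{k \ge 1}: at least
#' \eqn{k} coordinates with disjoint sets; for \eqn{k = 0}: all coordinates
#' intersect), and the maximum clique is found with
#' [igraph::clique_num()]. Candidate ordering is deterministic
#' (lexicographic per position via [utils::combn()]), so results are
#' reproducible.
#'
#' @inheritParams potentialClasses
#' @param cap Maximum number of candidate classes (default `1e4`); larger
#'   instances abort with advice to use the analytic bounds.
#' @return Integer, the exact maximum family size.
#' @examples
#' exhaustiveMaxDiscriminating(c(2, 2), 4, k = 1)   # 4, matching the bounds
#' exhaustiveMaxDiscriminating(2, 4, k = 0)         # 3 = choose(3, 1)
#' @export
exhaustiveMaxDiscriminating <- function(structure, alphabetSize, k,
                                        cap = 1e4) {
  A <- .checkAlphabetSize(alphabetSize)
  if (A > 30L)
    stop("exhaustive search supports alphabet sizes up to 30")
  e <- .checkStructure(structure, A)
  n <- length(e)
  k <- as.integer(k)
  if (k < 0L || k > n) stop("'k' must be in 0..n = ", n)
  total <- prod(choose(A, e))
  if (total > cap)
    stop("instance has ", format(total, big.mark = ","),
         " candidate classes (> cap = ", cap,
         "); use the analytic bounds instead")
  # per-position subsets as bitmasks, deterministic lexicographic order
  subsetMasks <- lapply(e, function(ei) {
    cmb <- utils::combn(A, ei)
    as.integer(colSums(matrix(bitwShiftL(1L, cmb - 1L), nrow = ei)))
  })
  grid <- as.matrix(expand.grid(lapply(subsetMasks, seq_along),
                                KEEP.OUT.ATTRS = FALSE))
  N <- nrow(grid)
  if (N == 1L) return(1L)
  disjointCount <- matrix(0L, N, N)
  for (i in seq_len(n)) {
    mi <- subsetMasks[[i]][grid[, i]]
    disjointCount <- disjointCount + (outer(mi, mi, bitwAnd) == 0L)
  }
  adj <- if (k == 0L) disjointCount == 0L else disjointCount >= k
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::clique_num(g))
}
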