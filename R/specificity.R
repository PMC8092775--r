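#' @include AllClasses.R
NULL

# positions as a plain list, letting helpers accept MotifClass or raw lists
.posOf <- function(x) if (is(x, "MotifClass")) positions(x) else x

#' Fixed positions of a motif class
#'
#' A motif position is *fixed* when it allows at most `threshold` residues
#' (default 10, i.e. half of the canonical alphabet); positions allowing more
#' are wildcard-like and carry no specificity. Only fixed positions
#' contribute to motif-discriminating position counts.
#'
#' @param motif A [MotifClass].
#' @param threshold Maximum allowed-set size for a position to count as
#'   fixed.
#' @return Integer vector of 1-based position indices.
#' @examples
#' fixedPositions(MotifClass("[LI].C.[DE]", "LIG_Rb"))   # 1 3 5
#' @export
fixedPositions <- function(motif, threshold = 10) {
  which(lengths(.posOf(motif)) <= threshold)
}

#' Motif-discriminating positions and alignments between motif classes
#'
#' For two classes of equal length \eqn{n}, the number of
#' motif-discriminating positions is
#' \deqn{mdp_{AB} = |\{i : A_i \cap B_i = \emptyset,\ |A_i| \le 10,\
#' |B_i| \le 10\}|,}
#' the count of fixed positions at which no amino acid can match both
#' regular expressions (`mdpEqualLength()`). `alignval()` is 1 iff some
#' position is fixed in both classes, i.e. the comparison is informative at
#' all.
#'
#' For classes of different lengths \eqn{n \ge m}, `alignments()` enumerates
#' the \eqn{n - m + 1} contiguous windows of the longer class against the
#' shorter one (no overhangs of the shorter motif), and the pairwise mdp is
#' the minimum equal-length mdp over the alignments with `alignval = 1`
#' (uninformative alignments are discarded). When no alignment is
#' informative the pair is reported with `mdp = 0` and `informative = FALSE`,
#' so it falls in the "not separated" bin.
#'
#' @param a,b [MotifClass] objects over the same alphabet.
#' @inheritParams fixedPositions
#' @return `pairSpecificity()` returns a `PairSpecificity` list with elements
#'   `mdp`, `informative`, `coincident` (identical position lists; defined
#'   for equal lengths only), `alignmentsTotal`, `alignmentsInformative` and
#'   an `alignmentTable` data frame (one row per alignment offset with its
#'   `alignval` and `mdp`). `mdp()` returns just the integer mdp value.
#' @examples
#' a <- MotifClass("[LI].C.[DE]", "A")
#' b <- MotifClass("[FI].W", "B")
#' mdp(a, b)                      # 1
#' pairSpecificity(a, b)$alignmentTable
#' @export
pairSpecificity <- function(a, b, threshold = 10) {
  pa <- .posOf(a)
  pb <- .posOf(b)
  swapped <- length(pa) < length(pb)
  if (swapped) { tmp <- pa; pa <- pb; pb <- tmp }
  n <- length(pa)
  m <- length(pb)
  sa <- lengths(pa)
  sb <- lengths(pb)
  offsets <- 0:(n - m)
  av <- integer(length(offsets))
  amdp <- integer(length(offsets))
  for (idx in seq_along(offsets)) {
    o <- offsets[idx]
    fixedBoth <- sa[(o + 1):(o + m)] <= threshold & sb <= threshold
    av[idx] <- as.integer(any(fixedBoth))
    cnt <- 0L
    for (j in which(fixedBoth))
      if (!any(pa[[o + j]] %in% pb[[j]])) cnt <- cnt + 1L
    amdp[idx] <- cnt
  }
  informative <- av == 1L
  res <- list(
    mdp = if (any(informative)) min(amdp[informative]) else 0L,
    informative = any(informative),
    coincident = n == m && identical(pa, pb),
    alignmentsTotal = length(offsets),
    alignmentsInformative = sum(informative),
    alignmentTable = data.frame(offset = offsets, alignval = av, mdp = amdp)
  )
  class(res) <- "PairSpecificity"
  res
}

#' @rdname pairSpecificity
#' @export
mdp <- function(a, b, threshold = 10) pairSpecificity(a, b, threshold)$mdp

#' @rdname pairSpecificity
#' @export
mdpEqualLength <- function(a, b, threshold = 10) {
  pa <- .posOf(a)
  pb <- .posOf(b)
  if (length(pa) != length(pb))
    stop("classes differ in length (", length(pa), " vs ", length(pb),
         "); use pairSpecificity() / mdp() for the alignment procedure")
  cnt <- 0L
  for (i in seq_along(pa))
    if (length(pa[[i]]) <= threshold && length(pb[[i]]) <= threshold &&
        !any(pa[[i]] %in% pb[[i]])) cnt <- cnt + 1L
  cnt
}

#' @rdname pairSpecificity
#' @export
alignval <- function(a, b, threshold = 10) {
  pa <- .posOf(a)
  pb <- .posOf(b)
  if (length(pa) != length(pb)) stop("alignval is defined for equal lengths")
  as.integer(any(lengths(pa) <= threshold & lengths(pb) <= threshold))
}

#' @rdname pairSpecificity
#' @export
alignments <- function(a, b) {
  pa <- .posOf(a)
  pb <- .posOf(b)
  if (length(pa) < length(pb)) { tmp <- pa; pa <- pb; pb <- tmp }
  m <- length(pb)
  lapply(0:(length(pa) - m), function(o)
    list(offset = o, longer = pa[(o + 1):(o + m)], shorter = pb))
}

#' @export
print.PairSpecificity <- function(x, ...) {
  cat("PairSpecificity: mdp =", x$mdp,
      if (!x$informative) "(no informative alignment)" else "",
      if (x$coincident) "(coincident classes)" else "", "\n")
  cat("  alignments:", x$alignmentsTotal, "total,",
      x$alignmentsInformative, "informative\n")
  invisible(x)
}

#' All-pairs motif specificity for a database
#'
#' Computes the `PairSpecificity` record for every unordered pair of classes
#' in a database: \eqn{\binom{N}{2}} comparisons for \eqn{N} classes (14706
#' for a 172-class database). Returns the per-pair table, the histogram of
#' mdp values, and summary fractions.
#'
#' @param db A [MotifDatabase] with at least two classes.
#' @inheritParams fixedPositions
#' @return List with elements `pairs` (data frame `idA`, `idB`, `mdp`,
#'   `informative`, `coincident`), `histogram` (named integer vector, counts
#'   per mdp value starting at 0), and `summary` (list with `nPairs`,
#'   `fracSeparated` = share with mdp >= 1, `fracCoincident`,
#'   `fracInformative`).
#' @examples
#' db <- exampleMotifDatabase()
#' ps <- pairwiseSpecificity(db)
#' ps$summary$nPairs == choose(length(db), 2)
#' @export
pairwiseSpecificity <- function(db, threshold = 10) {
  stopifnot(is(db, "MotifDatabase"))
  N <- length(db)
  if (N < 2L) stop("need at least two classes")
  ids <- identifier(db)
  poss <- lapply(motifClasses(db), positions)
  nPairs <- N * (N - 1L) / 2L
  idA <- character(nPairs); idB <- character(nPairs)
  vmdp <- integer(nPairs); vinf <- logical(nPairs); vcoi <- logical(nPairs)
  k <- 0L
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      k <- k + 1L
      ps <- pairSpecificity(poss[[i]], poss[[j]], threshold = threshold)
      idA[k] <- ids[i]; idB[k] <- ids[j]
      vmdp[k] <- ps$mdp; vinf[k] <- ps$informative; vcoi[k] <- ps$coincident
    }
  }
  hist <- table(factor(vmdp, levels = 0:max(vmdp)))
  list(
    pairs = data.frame(idA = idA, idB = idB, mdp = vmdp,
                       informative = vinf, coincident = vcoi,
                       stringsAsFactors = FALSE),
    histogram = stats::setNames(as.integer(hist), names(hist)),
    summary = list(nPairs = nPairs,
                   fracSeparated = mean(vmdp >= 1L),
                   fracCoincident = mean(vcoi),
                   fracInformative = mean(vinf))
  )
}
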