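#' @include alphabet.R
NULL

.mixtureCounts <- function(mixture) {
  if (is.data.frame(mixture)) {
    cc <- intersect(c("count", "counts", "frequency", "freq"),
                    tolower(colnames(mixture)))
    if (length(cc) == 0L)
      stop("mixture data frame needs a 'count' or 'frequency' column")
    x <- mixture[[match(cc[1L], tolower(colnames(mixture)))]]
  } else {
    x <- mixture
  }
  x <- as.numeric(x)
  if (length(x) < 1L || anyNA(x) || any(x < 0))
    stop("mixture must hold non-negative counts or frequencies")
  if (sum(x) <= 0) stop("mixture has no positive entry")
  x
}

#' Effective number of post-translational modifications
#'
#' `shannonEntropy()` computes the Shannon entropy (in bits) of a mixture of
#' modification counts or relative frequencies,
#' \eqn{H = \sum_i -p_i \log_2 p_i} with the convention
#' \eqn{0 \log 0 = 0}; frequencies are normalised to sum to one first.
#' `effectiveNumber()` converts it into the effective number of
#' equally-frequent categories, \eqn{2^H} — the same device used for the
#' effective number of species in ecology — and also reports its
#' nearest-integer rounding, which is the value used when expanding the
#' amino acid alphabet. `expandedAlphabetSize()` assembles the expanded
#' alphabet size as base + selenocysteine + effective modifications, e.g.
#' \eqn{20 + 1 + 12 = 33}.
#'
#' @param mixture Numeric vector of non-negative counts/frequencies, or a
#'   data frame with a `count` (or `frequency`) column such as returned by
#'   [readPtmTable()] or [samplePtmMixture()].
#' @param base Unmodified alphabet size (default 20).
#' @param includeSelenocysteine Add one symbol for selenocysteine.
#' @param effectiveModifications Integer count of effective modifications,
#'   typically `effectiveNumber(mixture)$rounded`.
#' @return `shannonEntropy()` the entropy in bits; `effectiveNumber()` a list
#'   with `entropy`, `value` (\eqn{2^H}) and `rounded`;
#'   `expandedAlphabetSize()` an integer.
#' @examples
#' shannonEntropy(c(0.5, 0.25, 0.25))        # 1.5 bits
#' effectiveNumber(rep(1, 12))$rounded       # 12
#' expandedAlphabetSize(20, TRUE, 12)        # 33
#' expandedAlphabetSize(20, TRUE, 8)         # 29
#' @export
shannonEntropy <- function(mixture) {
  x <- .mixtureCounts(mixture)
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @rdname shannonEntropy
#' @export
effectiveNumber <- function(mixture) {
  H <- shannonEntropy(mixture)
  list(entropy = H, value = 2^H, rounded = as.integer(round(2^H)))
}

#' @rdname shannonEntropy
#' @export
expandedAlphabetSize <- function(base = 20, includeSelenocysteine = TRUE,
                                 effectiveModifications = 0) {
  stopifnot(base >= 2, effectiveModifications >= 0)
  as.integer(base + as.integer(isTRUE(includeSelenocysteine)) +
               effectiveModifications)
}

#' Read a post-translational modification frequency table
#'
#' Loads a two-column tab-separated table (modification name, count);
#' `#`-prefixed lines are skipped. A packaged illustrative table mirroring
#' the twelve dominant modification types in curated protein databases ships
#' as `system.file("extdata", "ptm_frequencies_synthetic.tsv", package =
#' "motifSpace")`; its counts are synthetic stand-ins, not curated values.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `name` and `count`.
#' @examples
#' tab <- readPtmTable(system.file("extdata", "ptm_frequencies_synthetic.tsv",
#'                                 package = "motifSpace"))
#' effectiveNumber(tab)$rounded
#' @export
readPtmTable <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", header = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expected at least two columns (name, count)")
  out <- data.frame(name = as.character(tab[[1L]]),
                    count = as.numeric(tab[[2L]]),
                    stringsAsFactors = FALSE)
  .mixtureCounts(out)
  out
}
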