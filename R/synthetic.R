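#' @include pipeline.R
NULL

# Default marginals emulating a curated SLiM class collection: lengths
# concentrated on 3-10 residues with a mode near 5, and a bimodal
# allowed-set-size distribution (most positions allow 1-3 residues or are
# wildcard-like with 19-20). These are test scaffolding approximating the
# qualitative shape of curated databases, not claims about any snapshot.
.defaultLengthDistribution <- function() {
  stats::setNames(c(0.08, 0.22, 0.28, 0.18, 0.10, 0.06, 0.05, 0.03), 3:10)
}

.defaultSizeDistribution <- function(alphabetSize = 20) {
  p <- numeric(alphabetSize)
  p[1:5] <- c(0.24, 0.14, 0.07, 0.03, 0.02)
  if (alphabetSize > 7L) p[6:(alphabetSize - 2L)] <- 0.005
  p[alphabetSize - 1L] <- 0.10
  p[alphabetSize] <- 1 - sum(p[-alphabetSize])
  stats::setNames(p, seq_len(alphabetSize))
}

#' Generate a synthetic ELM-like motif database
#'
#' Samples a seeded [MotifDatabase] with the statistical structure the
#' analysis assumes: class lengths from `lengthDistribution` (default mass
#' on 3–10 residues, mode near 5), per-position allowed-set sizes from the
#' bimodal `sizeDistribution` (most positions allow 1–3 residues or are
#' wildcard-like), allowed sets drawn uniformly among subsets of the drawn
#' size, and heavy-tailed known-instance counts (log-normal, spanning
#' orders of magnitude). A fraction of classes is cloned into same-name
#' near-duplicates that overlap at every position (`mdp == 0`) with a
#' strictly lower instance count — exactly the redundancy that
#' [deduplicate()] removes.
#'
#' @param nClasses Total number of classes, including planted duplicates.
#' @param lengthDistribution Named numeric vector of probabilities over
#'   lengths (names are the lengths); normalised internally.
#' @param sizeDistribution Named numeric vector of probabilities over
#'   allowed-set sizes `1..length(alphabet)`; normalised internally.
#' @param duplicateFraction Fraction of classes planted as same-name
#'   redundant clones.
#' @param seed Integer seed; the same seed reproduces the database
#'   bit-for-bit.
#' @param alphabet Residue alphabet.
#' @return A [MotifDatabase]; the generator configuration (including the
#'   seed and the identifiers of planted duplicates) is stored in its
#'   provenance.
#' @examples
#' db <- sampleMotifDatabase(172, seed = 1)
#' length(db)
#' identical(identifier(sampleMotifDatabase(20, seed = 3)),
#'           identifier(sampleMotifDatabase(20, seed = 3)))
#' @export
sampleMotifDatabase <- function(nClasses = 172,
                                lengthDistribution =
                                  .defaultLengthDistribution(),
                                sizeDistribution = NULL,
                                duplicateFraction = 0.05,
                                seed = 1,
                                alphabet = motifAlphabet()) {
  .checkAlphabet(alphabet)
  A <- length(alphabet)
  if (is.null(sizeDistribution))
    sizeDistribution <- .defaultSizeDistribution(A)
  stopifnot(nClasses >= 1, duplicateFraction >= 0, duplicateFraction < 1)
  lengths <- as.integer(names(lengthDistribution))
  lp <- lengthDistribution / sum(lengthDistribution)
  sizes <- as.integer(names(sizeDistribution))
  sp <- sizeDistribution / sum(sizeDistribution)

  nDup <- as.integer(round(duplicateFraction * nClasses))
  nBase <- nClasses - nDup
  if (nBase < 1L) stop("duplicateFraction leaves no base classes")
  width <- max(3L, nchar(as.character(nClasses)))

  .withSeed(seed, {
    # terminal positions are drawn from the size distribution truncated at
    # 10 allowed residues: curated class tables are flank-trimmed, so their
    # first and last positions are always specific
    spTerm <- sp * (sizes <= 10L)
    base <- lapply(seq_len(nBase), function(i) {
      len <- sample(lengths, 1L, prob = lp)
      pos <- lapply(seq_len(len), function(j) {
        terminal <- j == 1L || j == len
        e <- sample(sizes, 1L, prob = if (terminal) spTerm else sp)
        sort(sample.int(A, e))
      })
      inst <- max(2L, as.integer(ceiling(stats::rlnorm(1, log(5), 1.2))))
      motifFromPositions(lapply(pos, function(ix) alphabet[ix]),
                         identifier = sprintf("SYN_%0*d", width, i),
                         name = sprintf("site_%0*d", width, i),
                         instances = inst, alphabet = alphabet)
    })
    dupOf <- if (nDup > 0L) sample.int(nBase, nDup) else integer(0)
    dups <- lapply(seq_along(dupOf), function(d) {
      parent <- base[[dupOf[d]]]
      pos <- positions(parent)
      # enlarge one position (superset keeps every coordinate intersecting,
      # hence mdp == 0 with the parent)
      j <- sample.int(length(pos), 1L)
      extra <- setdiff(alphabet, pos[[j]])
      if (length(extra))
        pos[[j]] <- c(pos[[j]], sample(extra,
                                       min(length(extra),
                                           sample.int(3L, 1L))))
      motifFromPositions(pos,
                         identifier = paste0(identifier(parent), "_v2"),
                         name = groupName(parent),
                         instances = knownInstances(parent) - 1L,
                         alphabet = alphabet)
    })
    MotifDatabase(c(base, dups), alphabet = alphabet,
                  provenance = list(
                    generator = "sampleMotifDatabase",
                    nClasses = nClasses, seed = seed,
                    duplicateFraction = duplicateFraction,
                    plantedDuplicates = vapply(dups, identifier,
                                               character(1)),
                    duplicateParents = vapply(seq_along(dupOf), function(d)
                      identifier(base[[dupOf[d]]]), character(1))))
  })
}

#' Worked-example motif database
#'
#' A small packaged database holding the classes used as worked examples
#' throughout the documentation: the Rb pocket B binding ligand class
#' `[LI].C.[DE]` (structure (2,20,1,20,2)), the toy class `[FI].W` whose
#' comparison with it yields one motif-discriminating position across three
#' alignments, and the six-member 1-discriminating block family of structure
#' (7,6). `preprocessingExamples()` returns the raw-versus-simplified
#' regular expression pairs exercising each preprocessing rule.
#'
#' @return `exampleMotifDatabase()` a [MotifDatabase] of 8 classes;
#'   `preprocessingExamples()` a data frame with columns `raw` and
#'   `simplified`.
#' @examples
#' db <- exampleMotifDatabase()
#' mdp(db[["LIG_Rb_LxCxE"]], db[["TOY_FIW"]])   # 1
#' preprocessingExamples()
#' @export
exampleMotifDatabase <- function() {
  ab <- motifAlphabet()
  blocks <- motifClasses(buildDiscriminatingSet(c(7, 6), ab))
  blocks <- lapply(seq_along(blocks), function(i) {
    m <- blocks[[i]]
    m@identifier <- sprintf("BLOCK76_%d", i)
    m@groupName <- sprintf("block family (7,6) member %d", i)
    m
  })
  classes <- c(list(
    MotifClass("[LI].C.[DE]", identifier = "LIG_Rb_LxCxE",
               name = "Rb pocket B binding ligand", instances = 10,
               alphabet = ab),
    MotifClass("[FI].W", identifier = "TOY_FIW",
               name = "toy tryptophan site", instances = 5, alphabet = ab)),
    blocks)
  MotifDatabase(classes, alphabet = ab,
                provenance = list(source = "worked examples"))
}

#' @rdname exampleMotifDatabase
#' @export
preprocessingExamples <- function() {
  data.frame(
    raw = c("[LIVMP].{0,2}(T)P..([ST])", "F..F$", "[KR]R.", "RV.PU"),
    simplified = c("[LIVMP](T)P..([ST])", "F..F", "[KR]R", "RV.PC"),
    rule = c("shortest version of variable-length repetition",
             "terminal anchor removal",
             "trimming of non-specific flanking positions",
             "modified-residue symbol mapping"),
    stringsAsFactors = FALSE)
}

#' Sample a synthetic post-translational modification mixture
#'
#' Draws modification counts log-uniformly over the requested number of
#' orders of magnitude, emulating the highly uneven abundance of
#' modification types in curated protein databases (where frequencies span
#' about five orders of magnitude).
#'
#' @param nModifications Number of modification types.
#' @param dynamicRangeOrders Orders of magnitude spanned by the counts.
#' @param seed Integer seed.
#' @return Data frame with columns `name` and `count`, usable with
#'   [shannonEntropy()] and [effectiveNumber()].
#' @examples
#' mix <- samplePtmMixture(522, 5, seed = 2)
#' eff <- effectiveNumber(mix)
#' eff$value > 1 && eff$value < 522
#' @export
samplePtmMixture <- function(nModifications = 522, dynamicRangeOrders = 5,
                             seed = 1) {
  stopifnot(nModifications >= 1, dynamicRangeOrders >= 0)
  .withSeed(seed, {
    counts <- 10^stats::runif(nModifications, 0, dynamicRangeOrders)
    data.frame(name = sprintf("mod_%03d", seq_len(nModifications)),
               count = counts, stringsAsFactors = FALSE)
  })
}
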