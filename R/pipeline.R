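#' @include specificity.R combinatorics.R occupancy.R
NULL

## ---- curation -------------------------------------------------------------

# connected components of an undirected adjacency matrix (tiny inputs)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Remove redundant same-name motif classes
#'
#' Motif databases contain minor variants of the same biological site:
#' classes sharing a functional-site name whose regular expressions are not
#' separated in sequence space (zero motif-discriminating positions). Within
#' each group of classes sharing `groupName`, classes linked by `mdp == 0`
#' are clustered and only the member with the highest known-instance count is
#' kept per cluster (ties keep the first in database order). Same-name
#' classes with `mdp >= 1` are genuinely distinct and all kept. The
#' operation is idempotent.
#'
#' @param db A [MotifDatabase].
#' @inheritParams fixedPositions
#' @return List with elements `database` (the curated [MotifDatabase]) and
#'   `removed` (data frame `removedId`, `keptId`, `groupName`).
#' @examples
#' db <- sampleMotifDatabase(40, duplicateFraction = 0.1, seed = 1)
#' dd <- deduplicate(db)
#' nrow(dd$removed)
#' @export
deduplicate <- function(db, threshold = 10) {
  stopifnot(is(db, "MotifDatabase"))
  groups <- split(seq_len(length(db)), groupName(db))
  inst <- knownInstances(db)
  ids <- identifier(db)
  drop <- integer(0)
  remLog <- list()
  for (g in groups) {
    if (length(g) < 2L) next
    adj <- matrix(FALSE, length(g), length(g))
    for (i in seq_along(g)[-length(g)])
      for (j in (i + 1L):length(g))
        if (mdp(db[[g[i]]], db[[g[j]]], threshold = threshold) == 0L)
          adj[i, j] <- adj[j, i] <- TRUE
    comp <- .components(adj | diag(TRUE, length(g)))
    for (cc in unique(comp)) {
      members <- g[comp == cc]
      if (length(members) < 2L) next
      keep <- members[which.max(inst[members])]
      gone <- setdiff(members, keep)
      drop <- c(drop, gone)
      remLog[[length(remLog) + 1L]] <-
        data.frame(removedId = ids[gone], keptId = ids[keep],
                   groupName = groupName(db)[keep],
                   stringsAsFactors = FALSE)
    }
  }
  removed <- if (length(remLog)) do.call(rbind, remLog) else
    data.frame(removedId = character(), keptId = character(),
               groupName = character(), stringsAsFactors = FALSE)
  keepIdx <- setdiff(seq_len(length(db)), drop)
  out <- db[keepIdx]
  out@provenance$deduplication <- removed
  list(database = out, removed = removed)
}

## ---- distributions --------------------------------------------------------

# Per-class potential-class value; mode "upper" follows potentialClasses(),
# mode "lower" uses the per-factor-floored constructive variant (truncated
# like the pigeonhole bound for k >= 2).
.potentialValue <- function(e, A, k, mode = c("upper", "lower")) {
  mode <- match.arg(mode)
  n <- length(e)
  if (mode == "upper" || k == 0L || k == n) {
    if (mode == "lower" && k > 0L && k == n) return(mnExact(e, A))
    # the per-position Erdős–Ko–Rado validity warning is a single-bound
    # diagnostic; database-level aggregation would repeat it per class
    if (k == 0L) return(suppressWarnings(m0Upper(e, A)))
    return(potentialClasses(e, A, k))
  }
  es <- sort(e, decreasing = TRUE)
  prod(A %/% es[seq_len(n - (k - 1L))])
}

# median convention matching a P(X >= x) curve: the largest observed value
# whose upper cumulative fraction is still >= 0.5
.cumulativeMedian <- function(values) {
  u <- sort(unique(values))
  frac <- vapply(u, function(t) mean(values >= t), numeric(1))
  max(u[frac >= 0.5])
}

.distributionSummary <- function(ids, values, nExcluded = 0L) {
  u <- sort(unique(values))
  curve <- data.frame(threshold = u,
                      fraction = vapply(u, function(t) mean(values >= t),
                                        numeric(1)))
  res <- list(values = data.frame(identifier = ids, value = values,
                                  stringsAsFactors = FALSE),
              curve = curve,
              median = .cumulativeMedian(values),
              medianInterpolated = stats::median(values),
              nExcluded = nExcluded)
  class(res) <- "DistributionSummary"
  res
}

#' @export
print.DistributionSummary <- function(x, ...) {
  cat("DistributionSummary over", nrow(x$values), "classes",
      if (x$nExcluded > 0) paste0("(", x$nExcluded, " excluded)"), "\n")
  cat("  median (P(X>=x) >= 0.5):", x$median,
      " interpolated:", x$medianInterpolated, "\n")
  invisible(x)
}

#' Database-level distributions of potential classes and occupancy
#'
#' For every class in the database, `potentialDistribution()` evaluates the
#' number of potential motif classes of that class's structure at
#' specificity level `k` (see [potentialClasses()]), and
#' `occupancyDistribution()` the corresponding potential sequence-space
#' occupancy (see [potentialOccupancy()], `k >= 1`). Classes shorter than
#' `k` positions are excluded (k motif-discriminating positions are
#' undefined for them); the exclusion count is reported. The summary holds
#' the per-class values, the upper cumulative curve
#' \eqn{P(X \ge x)} (non-increasing, starting at 1), and the median taken as
#' the largest value whose cumulative fraction is at least 0.5 (a standard
#' interpolated median is reported alongside).
#'
#' @param db A [MotifDatabase].
#' @inheritParams potentialClasses
#' @param mode `"upper"` (default, the reported bound) or `"lower"` (the
#'   per-factor-floored constructive variant), for
#'   `potentialDistribution()`.
#' @return A `DistributionSummary` list: `values`, `curve`, `median`,
#'   `medianInterpolated`, `nExcluded`.
#' @examples
#' db <- exampleMotifDatabase()
#' potentialDistribution(db, k = 1)$median
#' occupancyDistribution(db, k = 1)$median   # exactly 1
#' @export
potentialDistribution <- function(db, alphabetSize = 20, k,
                                  mode = c("upper", "lower")) {
  stopifnot(is(db, "MotifDatabase"))
  mode <- match.arg(mode)
  if (length(db) == 0L) stop("empty database")
  A <- .checkAlphabetSize(alphabetSize)
  k <- as.integer(k)
  structs <- motifStructure(db)
  ok <- lengths(structs) >= k
  if (!any(ok)) stop("no class has length >= k = ", k)
  vals <- vapply(structs[ok], .potentialValue, numeric(1),
                 A = A, k = k, mode = mode)
  .distributionSummary(identifier(db)[ok], vals, nExcluded = sum(!ok))
}

#' @rdname potentialDistribution
#' @export
occupancyDistribution <- function(db, alphabetSize = 20, k) {
  stopifnot(is(db, "MotifDatabase"))
  if (length(db) == 0L) stop("empty database")
  k <- as.integer(k)
  if (k < 1L) stop("occupancy distributions require k >= 1")
  A <- .checkAlphabetSize(alphabetSize)
  structs <- motifStructure(db)
  ok <- lengths(structs) >= k
  if (!any(ok)) stop("no class has length >= k = ", k)
  vals <- vapply(structs[ok], potentialOccupancy, numeric(1),
                 alphabetSize = A, k = k)
  .distributionSummary(identifier(db)[ok], vals, nExcluded = sum(!ok))
}

#' Median potential classes across alphabet sizes
#'
#' Recomputes the median number of potential motif classes for every
#' combination of alphabet size and specificity level `k`, in both bound
#' modes (`"upper"`: single end floor; `"lower"`: per-factor floor, the
#' constructive variant), and reports the fold change relative to the
#' baseline alphabet (default 20).
#'
#' @param db A [MotifDatabase].
#' @param alphabetSizes Integer vector of alphabet sizes to sweep.
#' @param ks Integer vector of specificity levels.
#' @param baseline Alphabet size used as fold-change reference.
#' @return Data frame with columns `alphabetSize`, `k`, `mode`, `median`,
#'   `foldChange`.
#' @examples
#' db <- exampleMotifDatabase()["LIG_Rb_LxCxE"]
#' sw <- alphabetSweep(db, c(20, 33), ks = 1)
#' subset(sw, mode == "lower")$foldChange   # 1, 8448/2000
#' @export
alphabetSweep <- function(db, alphabetSizes = 20:40, ks = 0:4,
                          baseline = 20) {
  stopifnot(is(db, "MotifDatabase"))
  grid <- expand.grid(alphabetSize = as.integer(alphabetSizes),
                      k = as.integer(ks),
                      mode = c("upper", "lower"),
                      stringsAsFactors = FALSE)
  grid$median <- mapply(function(A, k, mode)
    potentialDistribution(db, A, k, mode = mode)$median,
    grid$alphabetSize, grid$k, grid$mode)
  base <- grid[grid$alphabetSize == baseline, ]
  key <- paste(grid$k, grid$mode)
  baseKey <- paste(base$k, base$mode)
  grid$foldChange <- grid$median / base$median[match(key, baseKey)]
  grid
}

## ---- robustness experiments ----------------------------------------------

.medianPerK <- function(db, A, ks) {
  vapply(ks, function(k) {
    structs <- motifStructure(db)
    if (!any(lengths(structs) >= k)) return(NA_real_)
    potentialDistribution(db, A, k)$median
  }, numeric(1))
}

.robustnessReport <- function(kind, parameters, ks, fullMedians, ...) {
  res <- c(list(kind = kind, parameters = parameters, ks = ks,
                fullMedians = fullMedians), list(...))
  class(res) <- "RobustnessReport"
  res
}

#' @export
print.RobustnessReport <- function(x, ...) {
  cat("RobustnessReport:", x$kind, "\n")
  cat("  parameters:",
      paste(names(x$parameters), unlist(x$parameters), sep = "=",
            collapse = ", "), "\n")
  cat("  k:", paste(x$ks, collapse = " "), "\n")
  invisible(x)
}

#' Robustness experiments on a motif database
#'
#' Three seeded experiments probing how database composition affects the
#' median number of potential motif classes:
#' \describe{
#'   \item{`subsampleExperiment()`}{draws `replicates` subsamples of a given
#'     fraction of classes without replacement and recomputes the medians
#'     per `k`, reporting the per-replicate fold change against the full
#'     database (incompleteness check).}
#'   \item{`specificitySplitExperiment()`}{sorts classes by their number of
#'     potential instances (fewer instances = more specific), splits the
#'     database at the median — with an odd count the middle class joins the
#'     more-specific half — and recomputes the medians per half (specificity
#'     bias check).}
#'   \item{`mismatchToleranceExperiment()`}{replaces one uniformly chosen
#'     position with the full alphabet in a seeded random share of classes,
#'     emulating mismatch tolerance. The modified subset is the prefix of a
#'     seeded permutation, so for a fixed seed the databases at increasing
#'     fractions are nested and the per-class potential counts can only
#'     decrease.}
#' }
#' All experiments are bit-reproducible given `(seed, parameters)` and leave
#' the caller's RNG state untouched.
#'
#' @param db A [MotifDatabase].
#' @param fraction Fraction of classes to subsample / modify, in `(0, 1]`
#'   (`[0, 1]` for the mismatch experiment).
#' @param replicates Number of subsample replicates.
#' @param seed Integer seed.
#' @inheritParams potentialClasses
#' @param ks Integer vector of specificity levels.
#' @return A `RobustnessReport` list; elements depend on the experiment and
#'   include `fullMedians`, per-replicate or per-half medians and
#'   `foldChange`. The mismatch experiment also returns the modified
#'   `database`.
#' @examples
#' db <- sampleMotifDatabase(30, seed = 7)
#' r <- subsampleExperiment(db, fraction = 0.25, replicates = 3, seed = 1,
#'                          ks = 0:2)
#' r$foldChange
#' @export
subsampleExperiment <- function(db, fraction = 0.25, replicates = 10,
                                seed = 1, alphabetSize = 20, ks = 0:8) {
  stopifnot(is(db, "MotifDatabase"), fraction > 0, fraction <= 1)
  A <- .checkAlphabetSize(alphabetSize)
  ks <- as.integer(ks)
  N <- length(db)
  nSub <- max(1L, as.integer(round(fraction * N)))
  full <- .medianPerK(db, A, ks)
  reps <- .withSeed(seed, {
    t(vapply(seq_len(replicates), function(r)
      .medianPerK(db[sample.int(N, nSub)], A, ks), numeric(length(ks))))
  })
  colnames(reps) <- paste0("k", ks)
  .robustnessReport("subsample",
                    list(fraction = fraction, replicates = replicates,
                         seed = seed, alphabetSize = A),
                    ks, full,
                    replicateMedians = reps,
                    foldChange = sweep(reps, 2L, full, `/`))
}

#' @rdname subsampleExperiment
#' @export
specificitySplitExperiment <- function(db, alphabetSize = 20, ks = 0:8) {
  stopifnot(is(db, "MotifDatabase"))
  if (length(db) < 4L) stop("need at least four classes to split")
  A <- .checkAlphabetSize(alphabetSize)
  ks <- as.integer(ks)
  inst <- vapply(motifStructure(db), function(e) prod(as.numeric(e)),
                 numeric(1))
  ord <- order(inst)           # stable: ties keep database order
  nSpecific <- ceiling(length(db) / 2)
  specific <- db[ord[seq_len(nSpecific)]]
  unspecific <- db[ord[(nSpecific + 1L):length(db)]]
  .robustnessReport("specificity_split",
                    list(alphabetSize = A, nSpecific = nSpecific),
                    ks, .medianPerK(db, A, ks),
                    specificMedians = .medianPerK(specific, A, ks),
                    unspecificMedians = .medianPerK(unspecific, A, ks))
}

#' @rdname subsampleExperiment
#' @export
mismatchToleranceExperiment <- function(db, fraction = 0.5, seed = 1,
                                        alphabetSize = 20, ks = 0:8) {
  stopifnot(is(db, "MotifDatabase"), fraction >= 0, fraction <= 1)
  A <- .checkAlphabetSize(alphabetSize)
  ks <- as.integer(ks)
  N <- length(db)
  ab <- alphabet(db)
  # one permutation and one position per class drawn for the WHOLE database,
  # so calls with the same seed but growing fractions modify nested subsets
  draws <- .withSeed(seed, {
    list(order = sample.int(N),
         pos = vapply(motifStructure(db), function(e)
           sample.int(length(e), 1L), integer(1)))
  })
  nMod <- ceiling(fraction * N)
  modified <- db
  if (nMod > 0L) {
    for (i in draws$order[seq_len(nMod)]) {
      m <- modified@classes[[i]]
      pos <- positions(m)
      pos[[draws$pos[i]]] <- ab
      modified@classes[[i]] <- motifFromPositions(
        pos, identifier = identifier(m), name = groupName(m),
        instances = knownInstances(m), alphabet = ab)
    }
  }
  full <- .medianPerK(db, A, ks)
  med <- .medianPerK(modified, A, ks)
  .robustnessReport("mismatch_tolerance",
                    list(fraction = fraction, seed = seed,
                         alphabetSize = A, nModified = nMod),
                    ks, full,
                    medians = med,
                    foldChange = med / full,
                    database = modified)
}

## ---- proteome arithmetic --------------------------------------------------

#' Order-of-magnitude proteome arithmetic for motif classes
#'
#' `instancesFromResidues()` converts a number of residues predicted to lie
#' in motif instances into an instance count by integer division with the
#' typical motif length (e.g. 1,980,000 residues at length 5 give 396,000
#' instances). `proteomeClassEstimate()` divides a proteome-wide instance
#' count by the instances-per-class rate, rounding to the nearest integer
#' (396,000 / 225 = 1760 classes).
#'
#' @param residues,totalInstances,instancesPerClass,motifLength Positive
#'   integers.
#' @return Integer estimate.
#' @examples
#' instancesFromResidues(1980000, 5)     # 396000
#' proteomeClassEstimate(396000, 225)    # 1760
#' @export
proteomeClassEstimate <- function(totalInstances, instancesPerClass) {
  if (instancesPerClass <= 0 || totalInstances <= 0)
    stop("arguments must be positive")
  as.integer(round(totalInstances / instancesPerClass))
}

#' @rdname proteomeClassEstimate
#' @export
instancesFromResidues <- function(residues, motifLength) {
  if (motifLength <= 0 || residues <= 0)
    stop("arguments must be positive")
  as.integer(residues %/% motifLength)
}
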