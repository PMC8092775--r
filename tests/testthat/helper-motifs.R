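# Shared fixtures and independent oracles for the test suite. The oracles
# deliberately re-derive quantities by naive enumeration so they stay
# independent of the package implementation they check.

# Naive recount of motif-discriminating positions: enumerate every
# no-overhang window of the longer class, drop windows without a
# fixed-fixed match, count disjoint fixed-fixed positions, take the minimum.
naiveMdp <- function(pa, pb, threshold = 10) {
  if (methods::is(pa, "MotifClass")) pa <- positions(pa)
  if (methods::is(pb, "MotifClass")) pb <- positions(pb)
  if (length(pa) < length(pb)) { tmp <- pa; pa <- pb; pb <- tmp }
  m <- length(pb)
  best <- NULL
  for (o in 0:(length(pa) - m)) {
    win <- pa[(o + 1):(o + m)]
    fixedBoth <- mapply(function(A, B)
      length(A) <= threshold && length(B) <= threshold, win, pb)
    if (!any(fixedBoth)) next
    cnt <- sum(mapply(function(A, B, f)
      f && length(intersect(A, B)) == 0, win, pb, fixedBoth))
    best <- if (is.null(best)) cnt else min(best, cnt)
  }
  if (is.null(best)) 0L else as.integer(best)
}

# random allowed-set list over an alphabet (sets in alphabet order)
randomPositions <- function(len, alphabet, maxSize = length(alphabet)) {
  lapply(seq_len(len), function(i) {
    k <- sample.int(maxSize, 1L)
    alphabet[sort(sample.int(length(alphabet), k))]
  })
}

randomMotif <- function(id, len, alphabet = motifAlphabet(),
                        maxSize = length(alphabet)) {
  motifFromPositions(randomPositions(len, alphabet, maxSize), id,
                     alphabet = alphabet)
}

# total-variation distance between an empirical sample and target probs
tvDistance <- function(sample, target) {
  lev <- names(target)
  emp <- table(factor(sample, levels = lev)) / length(sample)
  sum(abs(as.numeric(emp) - as.numeric(target / sum(target)))) / 2
}
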