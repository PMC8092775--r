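rb <- MotifClass("[LI].C.[DE]", "RB")
fiw <- MotifClass("[FI].W", "FIW")

test_that("fixed positions are those allowing at most ten residues", {
  expect_identical(fixedPositions(rb), c(1L, 3L, 5L))
  wild <- motifFromPositions(rep(list(motifAlphabet()), 4), "w")
  expect_length(fixedPositions(wild), 0L)
  notP <- MotifClass("[^P]A", "np", preprocess = FALSE)
  expect_identical(fixedPositions(notP), 2L)   # 19 allowed > 10
  expect_identical(fixedPositions(notP, threshold = 19), c(1L, 2L))
})

test_that("equal-length mdp and alignval reproduce the worked comparison", {
  a <- MotifClass("[LI].C", "a")
  b <- MotifClass("[FI].W", "b")
  expect_identical(mdpEqualLength(a, b), 1L)
  expect_identical(alignval(a, b), 1L)
  # the middle window of the longer class against [FI].W is uninformative
  mid <- motifFromPositions(list(motifAlphabet(), "C", motifAlphabet()),
                            "mid")
  expect_identical(alignval(mid, b), 0L)
  expect_identical(mdpEqualLength(rb, rb), 0L)
  wild <- motifFromPositions(rep(list(motifAlphabet()), 3), "w")
  expect_identical(alignval(wild, wild), 0L)
  expect_error(mdpEqualLength(rb, b), "length")
})

test_that("alignment enumeration yields every no-overhang window", {
  al <- alignments(rb, fiw)
  expect_length(al, 3L)
  expect_identical(al[[1]]$longer, positions(rb)[1:3])
  expect_length(alignments(rb, rb), 1L)
  a7 <- motifFromPositions(rep(list("A"), 7), "a7")
  a3 <- motifFromPositions(rep(list("C"), 3), "a3")
  expect_length(alignments(a7, a3), 5L)
  expect_length(alignments(a3, a7), 5L)   # order-insensitive
})

test_that("general mdp minimises over informative alignments", {
  ps <- pairSpecificity(rb, fiw)
  expect_identical(ps$mdp, 1L)
  expect_identical(ps$alignmentsTotal, 3L)
  expect_identical(ps$alignmentsInformative, 2L)
  expect_identical(ps$alignmentTable$mdp[ps$alignmentTable$alignval == 1],
                   c(1L, 2L))
  expect_true(ps$informative)
  expect_false(ps$coincident)

  self <- pairSpecificity(rb, rb)
  expect_identical(self$mdp, 0L)
  expect_true(self$coincident)

  wild <- motifFromPositions(rep(list(motifAlphabet()), 5), "w")
  pw <- pairSpecificity(wild, rb)
  expect_identical(pw$mdp, 0L)
  expect_false(pw$informative)
})

test_that("mdp is symmetric, bounded by fixed positions, and matches the naive recount", {
  set.seed(13)
  ab6 <- motifAlphabet(6)
  for (rep in 1:60) {
    a <- randomMotif("a", sample(1:4, 1), ab6)
    b <- randomMotif("b", sample(1:4, 1), ab6)
    thr <- 3   # half the 6-letter alphabet plays the role of the 10 cutoff
    m1 <- mdp(a, b, threshold = thr)
    expect_identical(m1, mdp(b, a, threshold = thr))
    expect_identical(m1, naiveMdp(a, b, threshold = thr))
    expect_lte(m1, min(length(fixedPositions(a, thr)),
                       length(fixedPositions(b, thr))))
  }
})

test_that("enlarging an allowed set never increases mdp", {
  set.seed(29)
  ab <- motifAlphabet()
  for (rep in 1:30) {
    a <- randomMotif("a", sample(2:5, 1), ab, maxSize = 12)
    b <- randomMotif("b", sample(2:5, 1), ab, maxSize = 12)
    before <- mdp(a, b)
    pos <- positions(a)
    j <- sample.int(length(pos), 1)
    extra <- setdiff(ab, pos[[j]])
    if (length(extra) == 0) next
    pos[[j]] <- c(pos[[j]], sample(extra, 1))
    a2 <- motifFromPositions(pos, "a2", alphabet = ab)
    expect_lte(mdp(a2, b), before)
  }
})

test_that("pairwise matrix covers every unordered pair with consistent summaries", {
  db <- sampleMotifDatabase(20, duplicateFraction = 0, seed = 5)
  ps <- pairwiseSpecificity(db)
  expect_identical(nrow(ps$pairs), as.integer(choose(20, 2)))
  expect_identical(sum(ps$histogram), as.integer(choose(20, 2)))
  expect_equal(ps$summary$fracSeparated, mean(ps$pairs$mdp >= 1))

  twin <- MotifDatabase(list(
    MotifClass("[LI].C.[DE]", "x1"), MotifClass("[LI].C.[DE]", "x2")))
  pt <- pairwiseSpecificity(twin)
  expect_identical(nrow(pt$pairs), 1L)
  expect_identical(pt$pairs$mdp, 0L)
  expect_true(pt$pairs$coincident)
  expect_identical(pt$summary$fracCoincident, 1)
})
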