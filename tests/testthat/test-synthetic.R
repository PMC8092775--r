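test_that("generated databases are valid, sized and seed-deterministic", {
  db <- sampleMotifDatabase(172, seed = 1)
  expect_s4_class(db, "MotifDatabase")
  expect_length(db, 172L)
  expect_true(validObject(db))
  expect_length(sampleMotifDatabase(1, duplicateFraction = 0, seed = 2), 1L)

  a <- sampleMotifDatabase(25, seed = 77)
  b <- sampleMotifDatabase(25, seed = 77)
  expect_identical(lapply(motifClasses(a), positions),
                   lapply(motifClasses(b), positions))
  expect_identical(knownInstances(a), knownInstances(b))
  c <- sampleMotifDatabase(25, seed = 78)
  expect_false(identical(lapply(motifClasses(a), positions),
                         lapply(motifClasses(c), positions)))
  # generation does not disturb the caller's RNG stream
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(sampleMotifDatabase(5, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("sampled marginals converge to the configured distributions", {
  db <- sampleMotifDatabase(5000, duplicateFraction = 0, seed = 10)
  structs <- motifStructure(db)

  lengthTarget <- motifSpace:::.defaultLengthDistribution()
  expect_lt(tvDistance(lengths(structs), lengthTarget), 0.05)

  sizeTarget <- motifSpace:::.defaultSizeDistribution(20)
  interior <- unlist(lapply(structs, function(e)
    if (length(e) > 2) e[2:(length(e) - 1)] else integer(0)))
  expect_lt(tvDistance(interior, sizeTarget), 0.05)

  # terminal positions follow the distribution truncated at ten residues
  terminals <- unlist(lapply(structs, function(e) e[c(1, length(e))]))
  truncTarget <- sizeTarget * (as.integer(names(sizeTarget)) <= 10)
  expect_true(all(terminals <= 10))
  expect_lt(tvDistance(terminals, truncTarget), 0.05)

  # a modest database still lands near the target length marginal
  small <- sampleMotifDatabase(172, duplicateFraction = 0, seed = 4)
  expect_lt(tvDistance(lengths(motifStructure(small)), lengthTarget), 0.15)
})

test_that("the worked-example database carries the documented classes", {
  db <- exampleMotifDatabase()
  expect_identical(motifStructure(db[["LIG_Rb_LxCxE"]]),
                   c(2L, 20L, 1L, 20L, 2L))
  expect_identical(mdp(db[["LIG_Rb_LxCxE"]], db[["TOY_FIW"]]), 1L)
  blocks <- db[grep("^BLOCK76_", names(db))]
  expect_length(blocks, 6L)
  expect_true(all(vapply(motifClasses(blocks), function(m)
    identical(motifStructure(m), c(7L, 6L)), logical(1))))

  tf <- tempfile(fileext = ".tsv")
  writeClassTable(db, tf)
  rt <- readClassTable(tf)
  expect_identical(lapply(motifClasses(rt), positions),
                   lapply(motifClasses(db), positions))
})

test_that("synthetic modification mixtures are seeded and span the range", {
  m1 <- samplePtmMixture(522, 5, seed = 6)
  m2 <- samplePtmMixture(522, 5, seed = 6)
  expect_identical(m1, m2)
  expect_identical(nrow(m1), 522L)
  expect_gt(max(m1$count) / min(m1$count), 1e3)
  eff <- effectiveNumber(m1)$value
  expect_gt(eff, 1)
  expect_lt(eff, 522)
  # uniform mixture: effective number equals the category count
  expect_equal(effectiveNumber(samplePtmMixture(12, 0, seed = 1))$value, 12)
})
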