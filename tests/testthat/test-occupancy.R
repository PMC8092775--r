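test_that("occupancy of a single class is its instance share of sequence space", {
  expect_equal(classOccupancy(c(2, 20, 1, 20, 2), 20), 0.0005)
  expect_equal(classOccupancy(c(20, 20, 20), 20), 1)
  n <- 4
  expect_equal(classOccupancy(rep(1, n), 20), 20^(-n))
})

test_that("potential occupancy follows the worked example and rejects k = 0", {
  e5 <- c(2, 20, 1, 20, 2)
  expect_identical(potentialOccupancy(e5, 20, 1), 1)
  expect_equal(potentialOccupancy(e5, 20, 2), 0.05)
  expect_error(potentialOccupancy(e5, 20, 0), "k = 0")
  expect_error(potentialOccupancy(e5, 20, 6), "1..n")
})

test_that("potential occupancy at k = 1 is exactly one for random structures", {
  set.seed(17)
  for (rep in 1:200) {
    A <- sample(20:40, 1)
    e <- sample(1:A, sample(1:12, 1), replace = TRUE)
    expect_identical(potentialOccupancy(e, A, 1), 1)
  }
})

test_that("potential occupancy is non-increasing in k and equals e_min/A at k = 2", {
  set.seed(23)
  for (rep in 1:40) {
    A <- sample(c(20, 29, 33), 1)
    # n >= 3 so that k = 2 uses the unfloored bound (at k = n the exact
    # floored |M(n)| replaces it and the identity need not hold)
    e <- sample(1:A, sample(3:8, 1), replace = TRUE)
    occ <- vapply(seq_along(e), function(k) potentialOccupancy(e, A, k),
                  numeric(1))
    expect_true(all(diff(occ) <= 1e-12))
    expect_equal(occ[2], min(e) / A)
  }
})

test_that("constructed 1-discriminating families never overfill sequence space", {
  set.seed(31)
  for (rep in 1:15) {
    e <- sample(1:20, sample(1:3, 1), replace = TRUE)
    fam <- buildDiscriminatingSet(e)
    expect_lte(classOccupancy(e, 20) * length(fam), 1 + 1e-12)
  }
})
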