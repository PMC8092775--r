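e5 <- c(2, 20, 1, 20, 2)

test_that("closed-form bounds reproduce the worked structure (2,20,1,20,2)", {
  expect_warning(v0 <- m0Upper(e5, 20), "Erd")
  expect_equal(v0, 361)
  expect_equal(m1Lower(e5, 20), 2000)
  expect_equal(mkUpper(e5, 20, 1), 2000)
  expect_equal(vapply(1:5, function(k) potentialClasses(e5, 20, k),
                      numeric(1)),
               c(2000, 100, 10, 1, 1))
  expect_equal(mnExact(e5, 20), 1)
  # single positions and simple products
  expect_equal(m0Upper(1, 7), 1)
  expect_equal(m1Lower(c(7, 6), 20), 6)
  expect_equal(m1Lower(c(4, 5), 20), 20)
  expect_equal(mkUpper(c(4, 5), 20, 1), 20)   # lower and upper meet
  expect_equal(mnExact(c(4, 4), 20), 5)
})

test_that("expanded alphabets scale the constructive bound as printed", {
  expect_equal(m1Lower(e5, 33), 8448)
  expect_equal(m1Lower(e5, 29), 5684)
  expect_equal(potentialClasses(c(1, 1, 2, 20), 20, 1), 4000)
  expect_equal(potentialClasses(c(8, 8, 8, 8), 20, 1), 39)
  expect_equal(mkUpper(c(8, 8, 8, 8), 20, 1), 2.5^4)
})

test_that("bounds are permutation-invariant and non-increasing in k", {
  perm <- c(20, 20, 2, 2, 1)
  for (k in 0:5)
    expect_equal(suppressWarnings(potentialClasses(perm, 20, k)),
                 suppressWarnings(potentialClasses(e5, 20, k)))
  set.seed(3)
  for (rep in 1:20) {
    e <- sample(1:20, sample(2:6, 1), replace = TRUE)
    p <- sample(e)
    ks <- seq_along(e)
    upper <- vapply(ks, function(k) mkUpper(e, 20, k), numeric(1))
    expect_true(all(diff(upper) <= 1e-9))
    vals <- vapply(0:length(e), function(k)
      suppressWarnings(potentialClasses(e, 20, k)), numeric(1))
    valsPerm <- vapply(0:length(e), function(k)
      suppressWarnings(potentialClasses(p, 20, k)), numeric(1))
    expect_equal(vals, valsPerm)
    # k = n is at most the k = n-1 bound
    expect_lte(vals[length(vals)], vals[length(vals) - 1])
  }
})

test_that("argument validation rejects out-of-range k and structures", {
  expect_error(potentialClasses(c(2, 2), 20, 3), "0..n")
  expect_error(mkUpper(c(2, 2), 20, 0), "1..n")
  expect_error(potentialClasses(c(0, 2), 20, 1), "structure")
  expect_error(potentialClasses(c(25, 2), 20, 1), "structure")
})

test_that("the constructive family attains its size and pairwise separation", {
  fam <- buildDiscriminatingSet(c(7, 6))
  expect_length(fam, 6L)
  # the first member uses the leading blocks of consecutive symbols
  expect_identical(positions(fam[[1]])[[1]], motifAlphabet()[1:7])
  expect_identical(positions(fam[[1]])[[2]], motifAlphabet()[1:6])
  # full-alphabet structure gives the single all-wildcard class
  expect_length(buildDiscriminatingSet(20), 1L)

  ab6 <- motifAlphabet(6)
  fam6 <- buildDiscriminatingSet(c(2, 3), ab6)
  expect_length(fam6, 6L)   # floor(6/2) * floor(6/3)
  prs <- utils::combn(length(fam6), 2)
  for (q in seq_len(ncol(prs))) {
    pa <- positions(fam6[[prs[1, q]]])
    pb <- positions(fam6[[prs[2, q]]])
    disjoint <- mapply(function(A, B) length(intersect(A, B)) == 0, pa, pb)
    expect_true(any(disjoint))
  }
})

test_that("exhaustive search matches bounds on tiny frozen instances", {
  expect_identical(exhaustiveMaxDiscriminating(c(2, 2), 4, 1), 4L)
  expect_identical(exhaustiveMaxDiscriminating(1, 3, 1), 3L)
  expect_identical(exhaustiveMaxDiscriminating(2, 4, 0), 3L)   # C(3,1)
  expect_identical(exhaustiveMaxDiscriminating(c(2, 2), 4, 2), 2L)
  expect_error(exhaustiveMaxDiscriminating(c(3, 3, 3), 6, 1, cap = 100),
               "cap")
})
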