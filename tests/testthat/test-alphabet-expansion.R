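test_that("Shannon entropy and effective numbers follow the closed forms", {
  expect_equal(shannonEntropy(rep(1, 4)), 2)
  expect_equal(shannonEntropy(1), 0)
  expect_equal(shannonEntropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(effectiveNumber(c(0.5, 0.25, 0.25))$value, 2^1.5)
  expect_equal(effectiveNumber(rep(7, 12))$value, 12)
  expect_identical(effectiveNumber(rep(7, 12))$rounded, 12L)
  # zero-frequency entries contribute nothing
  expect_equal(shannonEntropy(c(2, 2, 0, 0)), 1)
  expect_error(shannonEntropy(c(0, 0)), "positive")
  expect_error(shannonEntropy(numeric()), "non-negative|positive")
})

test_that("effective number obeys the Jensen bounds and count rescaling", {
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(2:50, 1)
    counts <- stats::rexp(n) + 1e-6
    eff <- effectiveNumber(counts)$value
    expect_gte(eff, 1)
    expect_lte(eff, n + 1e-9)
    expect_equal(effectiveNumber(counts * 1234.5)$value, eff)
  }
  # equality only at the uniform distribution
  expect_equal(effectiveNumber(rep(3, 9))$value, 9)
})

test_that("expanded alphabet sizes assemble base + selenocysteine + modifications", {
  expect_identical(expandedAlphabetSize(20, TRUE, 12), 33L)
  expect_identical(expandedAlphabetSize(20, TRUE, 8), 29L)
  expect_identical(expandedAlphabetSize(20, FALSE, 0), 20L)
  expect_length(motifAlphabet(33), 33L)
})

test_that("the packaged modification table loads and behaves like an uneven mixture", {
  tab <- readPtmTable(system.file("extdata", "ptm_frequencies_synthetic.tsv",
                                  package = "motifSpace"))
  expect_identical(colnames(tab), c("name", "count"))
  expect_identical(nrow(tab), 12L)
  eff <- effectiveNumber(tab)
  expect_gt(eff$value, 1)
  expect_lt(eff$value, 12)   # uneven mixture: strictly fewer than 12
})
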