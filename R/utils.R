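# Internal helpers shared across the package.

# Floor with a tiny additive tolerance so that products of rationals such as
# (20/2)*(20/20)*... that are mathematically integral are not pushed below the
# integer by floating-point rounding. The tolerance (1e-9) is far below the
# unit spacing of any bound computed here.
.floorTol <- function(x) floor(x + 1e-9)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
.withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validate a motif structure (tuple of allowed-set sizes) against an alphabet
# size; returns it as an integer vector.
.checkStructure <- function(structure, alphabetSize) {
  e <- as.integer(structure)
  if (length(e) < 1L || anyNA(e))
    stop("'structure' must be a non-empty integer vector")
  if (any(e < 1L) || any(e > alphabetSize))
    stop("structure entries must lie in 1..alphabetSize (",
         alphabetSize, "); got (", paste(e, collapse = ","), ")")
  e
}

.checkAlphabetSize <- function(alphabetSize) {
  A <- as.integer(alphabetSize)
  if (length(A) != 1L || is.na(A) || A < 2L)
    stop("'alphabetSize' must be a single integer >= 2")
  A
}
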