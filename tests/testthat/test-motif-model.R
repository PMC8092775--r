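test_that("regex parsing expands the documented dialect", {
  pos <- parseMotifRegex("[LI].C.[DE]")
  expect_identical(lengths(pos), c(2L, 20L, 1L, 20L, 2L))
  expect_identical(pos[[1]], c("I", "L"))        # alphabet order
  expect_identical(pos[[3]], "C")
  expect_identical(pos[[2]], motifAlphabet())

  expect_identical(parseMotifRegex("A"), list("A"))
  expect_identical(parseMotifRegex("[^P]")[[1]], setdiff(motifAlphabet(), "P"))
  # fixed repetition expands in place; parens are transparent
  expect_identical(lengths(parseMotifRegex("P{3}(T)")), c(1L, 1L, 1L, 1L))
  # symbol map applies to literals and inside classes
  expect_identical(parseMotifRegex("U")[[1]], "C")
  expect_identical(parseMotifRegex("[US]")[[1]], c("C", "S"))
})

test_that("unsupported constructs fail with a named construct and offset", {
  expect_error(parseMotifRegex("A|B"), "'\\|'.*offset 2")
  expect_error(parseMotifRegex("A*"), "'\\*'")
  expect_error(parseMotifRegex("A+"), "'\\+'")
  expect_error(parseMotifRegex("^AC"), "anchor")
  expect_error(parseMotifRegex("A{1,3}"), "bounded repetition")
  expect_error(parseMotifRegex("AZC"), "symbol 'Z'")
  expect_error(parseMotifRegex("[AC"), "unterminated")
  expect_s3_class(tryCatch(parseMotifRegex("A|B"), error = identity),
                  "motifParseError")
})

test_that("preprocessing applies the four curation rules in order", {
  ex <- preprocessingExamples()
  for (i in seq_len(nrow(ex)))
    expect_identical(preprocessRegex(ex$raw[i])$regex, ex$simplified[i],
                     label = ex$raw[i])
  # rule log is informative
  expect_match(preprocessRegex("F..F$")$log, "anchor", all = FALSE)
  expect_match(preprocessRegex("RV.PU")$log, "mapped", all = FALSE)
  # fully wildcard motifs are rejected
  expect_error(preprocessRegex("..."), "fully wildcard")
  expect_error(preprocessRegex("[^A]..$"), "fully wildcard")
})

test_that("preprocessing is idempotent and trimming spares specific flanks", {
  raws <- c(preprocessingExamples()$raw, "[KR]R.", "^M{0,1}([ED])",
            "..[ST]P.", "[RK].{0,2}L[^P]")
  for (r in raws) {
    once <- preprocessRegex(r)$regex
    expect_identical(preprocessRegex(once)$regex, once, label = r)
  }

  # property: trimming removes only >= 11-residue positions, from the ends
  set.seed(41)
  ab <- motifAlphabet()
  for (rep in 1:40) {
    pos <- randomPositions(sample(2:6, 1), ab)
    rx <- canonicalRegex(pos, ab)
    res <- tryCatch(preprocessRegex(rx), error = identity)
    sizes <- lengths(pos)
    if (!any(sizes <= 10)) {
      expect_s3_class(res, "error")
    } else {
      keep <- range(which(sizes <= 10))
      kept <- parseMotifRegex(res$regex)
      expect_identical(kept, pos[keep[1]:keep[2]])
      expect_lte(length(kept[[1]]), 10)
      expect_lte(length(kept[[length(kept)]]), 10)
    }
  }
})

test_that("canonical regex round-trips generated position lists", {
  set.seed(7)
  ab <- motifAlphabet()
  for (rep in 1:25) {
    pos <- randomPositions(sample(1:6, 1), ab)
    expect_identical(parseMotifRegex(canonicalRegex(pos, ab)), pos)
  }
  ab4 <- motifAlphabet(4)
  pos <- list(c("A", "C"), ab4, "D")
  expect_identical(parseMotifRegex(canonicalRegex(pos, ab4), ab4), pos)
})

test_that("structure, instance counting and matching agree with enumeration", {
  m <- MotifClass("[LI].C.[DE]", "LIG_Rb")
  expect_identical(motifStructure(m), c(2L, 20L, 1L, 20L, 2L))
  expect_equal(countInstances(m), 1600)
  expect_equal(countInstances(c(1, 1, 1)), 1)
  expect_equal(countInstances(c(3, 4)), 12)
  expect_identical(motifStructure(MotifClass("A", "a")), 1L)
  # un-trimmed parse keeps the trailing wildcard
  expect_identical(lengths(parseMotifRegex("[^P]..")), c(19L, 20L, 20L))

  expect_true(isInstance("IACDD", m))
  expect_false(isInstance("IACDP", m))
  expect_error(isInstance("IACD", m), "length")
  wild <- motifFromPositions(rep(list(motifAlphabet()), 3), "wild")
  expect_true(isInstance("WYH", wild))

  # countInstances equals exhaustive enumeration of matching sequences
  ab4 <- motifAlphabet(4)
  set.seed(11)
  for (rep in 1:10) {
    mm <- randomMotif("r", sample(1:3, 1), ab4)
    allSeqs <- do.call(expand.grid,
                       c(rep(list(ab4), motifLength(mm)),
                         stringsAsFactors = FALSE))
    matches <- sum(apply(allSeqs, 1, function(s)
      isInstance(unname(s), mm)))
    expect_equal(countInstances(mm), matches)
  }
})

test_that("class tables round-trip through TSV and JSON", {
  db <- sampleMotifDatabase(15, duplicateFraction = 0, seed = 99)
  fields <- function(d) lapply(motifClasses(d), function(m)
    list(identifier(m), groupName(m), sourceRegex(m), positions(m),
         knownInstances(m)))

  tf <- tempfile(fileext = ".tsv")
  writeClassTable(db, tf)
  expect_identical(fields(readClassTable(tf)), fields(db))

  tj <- tempfile(fileext = ".json")
  writeClassTable(db, tj, format = "json")
  expect_identical(fields(readClassTable(tj, format = "json")), fields(db))

  # ELM dialect: '#' metadata lines, aliased headers, quoted fields
  toy <- readClassTable(system.file("extdata", "toy_classes.tsv",
                                    package = "motifSpace"))
  expect_identical(identifier(toy), c("LIG_Rb_LxCxE", "TOY_FIW", "TOY_TRAF"))
  expect_identical(knownInstances(toy), c(10L, 5L, 3L))
  expect_identical(motifStructure(toy[["LIG_Rb_LxCxE"]]),
                   c(2L, 20L, 1L, 20L, 2L))
})

test_that("strict mode aborts on bad rows, lenient mode skips and logs them", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("identifier\tname\tregex\tinstances",
               "OK1\tsite a\t[LI].C.[DE]\t4",
               "BAD\tsite b\tA|B\t1",
               "OK2\tsite c\t[FI].W\t2"), tf)
  expect_error(readClassTable(tf), "BAD")
  db <- readClassTable(tf, strict = FALSE)
  expect_identical(identifier(db), c("OK1", "OK2"))
  expect_match(db@provenance$skipped, "BAD", all = FALSE)
  # missing required column
  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("identifier\tregex", "X\tA"), tf2)
  expect_error(readClassTable(tf2), "missing required column")
})

test_that("database container validates and subsets", {
  db <- exampleMotifDatabase()
  expect_length(db, 8L)
  expect_identical(names(db)[1], "LIG_Rb_LxCxE")
  expect_identical(identifier(db[["TOY_FIW"]]), "TOY_FIW")
  sub <- db[c(1, 2)]
  expect_s4_class(sub, "MotifDatabase")
  expect_length(sub, 2L)
  dup <- motifClasses(db)[c(1, 1)]
  expect_error(MotifDatabase(dup), "duplicated identifiers")
  expect_error(motifFromPositions(list(character()), "x"), "position")
})
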