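#' @include AllGenerics.R
NULL

#' MotifClass: a linear motif class as allowed-amino-acid sets
#'
#' A linear motif class of length \eqn{n} is a sequence
#' \eqn{(A_1, \dots, A_n)} of allowed-amino-acid sets over a fixed alphabet;
#' a motif instance is any sequence \eqn{(a_1,\dots,a_n)} with
#' \eqn{a_i \in A_i}. The constructor takes an ELM-style regular expression,
#' preprocesses it (see [preprocessRegex()]) and expands it into position
#' sets (see [parseMotifRegex()]).
#'
#' @param regex Character scalar, the source regular expression.
#' @param identifier Character scalar, unique class identifier.
#' @param name Functional-site (group) name; defaults to the identifier.
#' @param instances Non-negative count of curated known instances.
#' @param alphabet Residue alphabet, see [motifAlphabet()].
#' @param symbolMap Named character vector mapping non-canonical letters to
#'   alphabet symbols; the default maps selenocysteine `U` to `C`.
#' @param preprocess Apply [preprocessRegex()] before parsing (default). When
#'   `FALSE` the regex must already be in the simplified dialect.
#'
#' @slot identifier,groupName,sourceRegex,regex Character scalars; `regex` is
#'   the preprocessed form actually parsed.
#' @slot positions List of character vectors, the allowed sets in alphabet
#'   order.
#' @slot knownInstances Integer, curated instance count.
#' @slot alphabet Character vector of residue symbols.
#' @slot preprocessLog Character vector of preprocessing rules applied.
#'
#' @return A `MotifClass` object.
#' @seealso [motifFromPositions()], [motifStructure()], [countInstances()],
#'   [isInstance()]
#' @examples
#' m <- MotifClass("[LI].C.[DE]", identifier = "LIG_Rb_LxCxE",
#'                 name = "Rb pocket B ligand", instances = 10)
#' motifStructure(m)   # (2, 20, 1, 20, 2)
#' countInstances(m)   # 1600
#' @aliases MotifClass-class
#' @export MotifClass
#' @exportClass MotifClass
MotifClass <- setClass("MotifClass",
  slots = c(identifier = "character",
            groupName = "character",
            sourceRegex = "character",
            regex = "character",
            positions = "list",
            knownInstances = "integer",
            alphabet = "character",
            preprocessLog = "character"))

setValidity("MotifClass", function(object) {
  msg <- character()
  for (s in c("identifier", "groupName", "sourceRegex", "regex"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, paste0("'", s, "' must be a single string"))
  if (length(object@alphabet) < 2L || anyDuplicated(object@alphabet))
    msg <- c(msg, "alphabet must hold >= 2 unique symbols")
  if (length(object@positions) < 1L)
    msg <- c(msg, "a motif class must have length >= 1")
  for (i in seq_along(object@positions)) {
    p <- object@positions[[i]]
    if (!is.character(p) || length(p) < 1L || anyDuplicated(p) ||
        !all(p %in% object@alphabet))
      msg <- c(msg, paste0("position ", i,
                           " is not a non-empty unique subset of the alphabet"))
  }
  if (length(object@knownInstances) != 1L || is.na(object@knownInstances) ||
      object@knownInstances < 0L)
    msg <- c(msg, "'knownInstances' must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' @rdname MotifClass
setMethod("initialize", "MotifClass", function(.Object, ...) {
  .Object <- callNextMethod(.Object, ...)
  # normalise allowed sets to alphabet order so identical() comparisons and
  # canonical regex emission are deterministic
  .Object@positions <- lapply(.Object@positions, function(p)
    .Object@alphabet[.Object@alphabet %in% p])
  .Object
})

# user-facing constructor (replaces the default generator call semantics)
#' @rdname MotifClass
#' @usage MotifClass(regex, identifier, name = identifier, instances = 0,
#'   alphabet = motifAlphabet(), symbolMap = c(U = "C"), preprocess = TRUE)
MotifClass <- function(regex, identifier, name = identifier, instances = 0,
                       alphabet = motifAlphabet(), symbolMap = c(U = "C"),
                       preprocess = TRUE) {
  .checkAlphabet(alphabet)
  if (preprocess) {
    pp <- preprocessRegex(regex, alphabet = alphabet, symbolMap = symbolMap)
    simplified <- pp$regex
    log <- pp$log
  } else {
    simplified <- regex
    log <- character()
  }
  pos <- parseMotifRegex(simplified, alphabet = alphabet, symbolMap = symbolMap)
  new("MotifClass", identifier = as.character(identifier),
      groupName = as.character(name), sourceRegex = as.character(regex),
      regex = simplified, positions = pos,
      knownInstances = as.integer(instances), alphabet = alphabet,
      preprocessLog = log)
}

#' Build a motif class directly from position sets
#'
#' Low-level constructor used when the allowed sets are already known (e.g.
#' by the constructive lower-bound builder or the synthetic generator). The
#' canonical regular expression is derived with [canonicalRegex()].
#'
#' @param positions List of character vectors, each a non-empty subset of
#'   `alphabet`.
#' @inheritParams MotifClass
#' @return A [MotifClass] object.
#' @examples
#' motifFromPositions(list(c("L", "I"), motifAlphabet(), "C"), "toy")
#' @export
motifFromPositions <- function(positions, identifier, name = identifier,
                               instances = 0, alphabet = motifAlphabet()) {
  .checkAlphabet(alphabet)
  rx <- canonicalRegex(positions, alphabet)
  new("MotifClass", identifier = as.character(identifier),
      groupName = as.character(name), sourceRegex = rx, regex = rx,
      positions = positions, knownInstances = as.integer(instances),
      alphabet = alphabet, preprocessLog = character())
}

#' MotifDatabase: an ordered collection of motif classes
#'
#' Holds an ordered list of [MotifClass] objects sharing one alphabet, plus
#' free-form provenance metadata (source, preprocessing log, generator
#' configuration). Class identifiers must be unique. Supports `length()`,
#' `names()`, `[` (sub-database) and `[[` (single class, by index or by
#' identifier).
#'
#' @param classes List of [MotifClass] objects.
#' @param alphabet Shared residue alphabet.
#' @param provenance Named list of metadata.
#' @return A `MotifDatabase` object.
#' @seealso [readClassTable()], [sampleMotifDatabase()],
#'   [exampleMotifDatabase()]
#' @examples
#' db <- exampleMotifDatabase()
#' length(db)
#' motifStructure(db[["LIG_Rb_LxCxE"]])
#' @aliases MotifDatabase-class
#' @export MotifDatabase
#' @exportClass MotifDatabase
MotifDatabase <- setClass("MotifDatabase",
  slots = c(classes = "list", alphabet = "character", provenance = "list"))

setValidity("MotifDatabase", function(object) {
  msg <- character()
  ok <- vapply(object@classes, is, logical(1), class2 = "MotifClass")
  if (!all(ok)) msg <- c(msg, "all elements of 'classes' must be MotifClass")
  if (all(ok)) {
    ids <- vapply(object@classes, identifier, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, paste0("duplicated identifiers: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    same <- vapply(object@classes, function(m)
      identical(alphabet(m), object@alphabet), logical(1))
    if (!all(same))
      msg <- c(msg, "all classes must share the database alphabet")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname MotifDatabase
#' @usage MotifDatabase(classes, alphabet = motifAlphabet(), provenance = list())
MotifDatabase <- function(classes, alphabet = motifAlphabet(),
                          provenance = list()) {
  new("MotifDatabase", classes = unname(classes), alphabet = alphabet,
      provenance = provenance)
}

## ---- accessors ------------------------------------------------------------

#' @rdname motif-accessors
setMethod("identifier", "MotifClass", function(x) x@identifier)
#' @rdname motif-accessors
setMethod("groupName", "MotifClass", function(x) x@groupName)
#' @rdname motif-accessors
setMethod("sourceRegex", "MotifClass", function(x) x@sourceRegex)
#' @rdname motif-accessors
setMethod("motifRegex", "MotifClass", function(x) x@regex)
#' @rdname motif-accessors
setMethod("positions", "MotifClass", function(x) x@positions)
#' @rdname motif-accessors
setMethod("knownInstances", "MotifClass", function(x) x@knownInstances)
#' @rdname motif-accessors
setMethod("alphabet", "MotifClass", function(x) x@alphabet)
#' @rdname motif-accessors
setMethod("motifLength", "MotifClass", function(x) length(x@positions))
#' @rdname motif-accessors
setMethod("motifStructure", "MotifClass", function(x)
  lengths(x@positions, use.names = FALSE))

#' @rdname motif-accessors
setMethod("motifClasses", "MotifDatabase", function(x) x@classes)
#' @rdname motif-accessors
setMethod("alphabet", "MotifDatabase", function(x) x@alphabet)
#' @rdname motif-accessors
setMethod("identifier", "MotifDatabase", function(x)
  vapply(x@classes, identifier, character(1)))
#' @rdname motif-accessors
setMethod("groupName", "MotifDatabase", function(x)
  vapply(x@classes, groupName, character(1)))
#' @rdname motif-accessors
setMethod("knownInstances", "MotifDatabase", function(x)
  vapply(x@classes, knownInstances, integer(1)))
#' @rdname motif-accessors
setMethod("motifStructure", "MotifDatabase", function(x)
  lapply(x@classes, motifStructure))

#' @describeIn MotifDatabase Number of classes.
#' @param x A `MotifDatabase`.
#' @export
setMethod("length", "MotifDatabase", function(x) length(x@classes))

#' @describeIn MotifDatabase Class identifiers.
#' @export
setMethod("names", "MotifDatabase", function(x) identifier(x))

#' @describeIn MotifDatabase Sub-database by index, identifier or logical.
#' @param i Index vector (integer, logical or identifier).
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "MotifDatabase", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, identifier(x))
  if (anyNA(i)) stop("unknown class selection")
  initialize(x, classes = x@classes[i])
})

#' @describeIn MotifDatabase Extract one class by index or identifier.
#' @export
setMethod("[[", "MotifDatabase", function(x, i, ...) {
  if (is.character(i)) {
    i <- match(i, identifier(x))
    if (is.na(i)) stop("unknown class identifier")
  }
  x@classes[[i]]
})

## ---- show -----------------------------------------------------------------

setMethod("show", "MotifClass", function(object) {
  cat("MotifClass", object@identifier,
      if (nzchar(object@groupName) && object@groupName != object@identifier)
        paste0("(", object@groupName, ")") else "", "\n")
  cat("  regex:     ", object@regex, "\n", sep = "")
  cat("  structure: (", paste(motifStructure(object), collapse = ","),
      ")  length ", motifLength(object), "\n", sep = "")
  cat("  instances: ", object@knownInstances, "  alphabet size ",
      length(object@alphabet), "\n", sep = "")
  invisible(object)
})

setMethod("show", "MotifDatabase", function(object) {
  cat("MotifDatabase with", length(object), "classes over a",
      length(object@alphabet), "letter alphabet\n")
  n <- length(object)
  shown <- seq_len(min(5L, n))
  for (i in shown)
    cat(sprintf("  %-20s %s\n", identifier(object@classes[[i]]),
                motifRegex(object@classes[[i]])))
  if (n > length(shown)) cat("  ... and", n - length(shown), "more\n")
  if (length(object@provenance))
    cat("provenance:", paste(names(object@provenance), collapse = ", "), "\n")
  invisible(object)
})
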