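#' @include alphabet.R
NULL

#' Accessors for motif classes and databases
#'
#' Standard accessor generics: `identifier()` and `groupName()` return the
#' class identifier and functional-site name, `sourceRegex()` the regular
#' expression as supplied, `motifRegex()` its preprocessed form,
#' `positions()` the ordered list of allowed-amino-acid sets,
#' `knownInstances()` the curated instance count, `alphabet()` the residue
#' alphabet, `motifLength()` the number of positions, and `motifStructure()`
#' the tuple of allowed-set sizes \eqn{(e_1,\dots,e_n)}. On a
#' `MotifDatabase`, vectorised accessors return one value per class and
#' `motifClasses()` returns the list of `MotifClass` objects.
#'
#' @param x A [MotifClass] or [MotifDatabase] object.
#' @return See the description; scalar per class, vectorised over databases.
#' @name motif-accessors
#' @examples
#' m <- MotifClass("[LI].C.[DE]", identifier = "LIG_Rb")
#' motifStructure(m)
#' positions(m)[[1]]
NULL

#' @rdname motif-accessors
#' @export
setGeneric("identifier", function(x) standardGeneric("identifier"))

#' @rdname motif-accessors
#' @export
setGeneric("groupName", function(x) standardGeneric("groupName"))

#' @rdname motif-accessors
#' @export
setGeneric("sourceRegex", function(x) standardGeneric("sourceRegex"))

#' @rdname motif-accessors
#' @export
setGeneric("motifRegex", function(x) standardGeneric("motifRegex"))

#' @rdname motif-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname motif-accessors
#' @export
setGeneric("knownInstances", function(x) standardGeneric("knownInstances"))

#' @rdname motif-accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' @rdname motif-accessors
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname motif-accessors
#' @export
setGeneric("motifStructure", function(x) standardGeneric("motifStructure"))

#' @rdname motif-accessors
#' @export
setGeneric("motifClasses", function(x) standardGeneric("motifClasses"))
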