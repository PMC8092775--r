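#' @include AllClasses.R
NULL

.defaultColumnAliases <- list(
  identifier = c("identifier", "accession", "elm_identifier", "elmidentifier",
                 "id"),
  name = c("name", "functional_site_name", "functionalsitename", "group_name",
           "site", "group"),
  regex = c("regex", "pattern", "regular_expression"),
  instances = c("instances", "known_instances", "#instances", "instance_count",
                "n_instances")
)

.resolveColumns <- function(found, columnAliases) {
  aliases <- .defaultColumnAliases
  if (!is.null(columnAliases))
    for (nm in names(columnAliases))
      aliases[[nm]] <- unique(c(columnAliases[[nm]], aliases[[nm]]))
  res <- vapply(names(aliases), function(field) {
    hit <- match(aliases[[field]], tolower(found))
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  missing <- names(res)[is.na(res)]
  if (length(missing))
    stop("class table is missing required column(s) ",
         paste(missing, collapse = ", "), "; found columns: ",
         paste(found, collapse = ", "))
  res
}

#' Read and write motif class tables
#'
#' `readClassTable()` loads a motif class table in the ELM "classes" TSV
#' dialect (tab-separated with a header, `#`-prefixed metadata lines skipped,
#' quoted fields allowed) or an equivalent JSON dump, preprocesses and parses
#' each regular expression, and returns a [MotifDatabase] with the
#' per-class preprocessing log attached to its provenance.
#' `writeClassTable()` is the lossless inverse for the canonical columns:
#' `readClassTable(writeClassTable(db))` reconstructs the same classes.
#'
#' Column names are matched case-insensitively against built-in aliases
#' (e.g. `Accession`/`ELMIdentifier` for the identifier,
#' `FunctionalSiteName` for the name, `#Instances` for the instance count);
#' `columnAliases` prepends additional aliases per field.
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @inheritParams MotifClass
#' @param strict When `TRUE` (default) any row whose regex fails to
#'   preprocess or parse aborts the read; when `FALSE` failing rows are
#'   skipped and collected in `provenance(db)$skipped`.
#' @param columnAliases Optional named list of extra column-name aliases for
#'   fields `identifier`, `name`, `regex`, `instances`.
#' @param db A [MotifDatabase].
#' @return `readClassTable()` a [MotifDatabase]; `writeClassTable()` the
#'   path, invisibly.
#' @examples
#' db <- exampleMotifDatabase()
#' tf <- tempfile(fileext = ".tsv")
#' writeClassTable(db, tf)
#' db2 <- readClassTable(tf)
#' identical(identifier(db), identifier(db2))
#' @export
readClassTable <- function(path, format = c("tsv", "json"),
                           alphabet = motifAlphabet(),
                           symbolMap = c(U = "C"), strict = TRUE,
                           columnAliases = NULL) {
  format <- match.arg(format)
  if (format == "json") return(.readClassJson(path, alphabet, symbolMap))
  # metadata lines start with '#'; filter them by hand because the ELM
  # dialect also uses '#' inside header names ("#Instances")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  cols <- .resolveColumns(colnames(tab), columnAliases)
  classes <- list()
  logs <- list()
  skipped <- character()
  for (r in seq_len(nrow(tab))) {
    id <- as.character(tab[[cols["identifier"]]][r])
    res <- tryCatch(
      MotifClass(as.character(tab[[cols["regex"]]][r]), identifier = id,
                 name = as.character(tab[[cols["name"]]][r]),
                 instances = as.integer(tab[[cols["instances"]]][r]),
                 alphabet = alphabet, symbolMap = symbolMap),
      error = function(e) e)
    if (inherits(res, "error")) {
      msg <- paste0("row ", r, " (", id, "): ", conditionMessage(res))
      if (strict) stop("failed to read class table: ", msg)
      skipped <- c(skipped, msg)
    } else {
      classes[[length(classes) + 1L]] <- res
      if (length(res@preprocessLog))
        logs[[id]] <- res@preprocessLog
    }
  }
  MotifDatabase(classes, alphabet = alphabet,
                provenance = list(source = path, format = "tsv",
                                  preprocessing = logs, skipped = skipped))
}

#' @rdname readClassTable
#' @export
writeClassTable <- function(db, path, format = c("tsv", "json")) {
  stopifnot(is(db, "MotifDatabase"))
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      alphabet = alphabet(db),
      classes = lapply(motifClasses(db), function(m) list(
        identifier = identifier(m), name = groupName(m),
        regex = sourceRegex(m), simplified = motifRegex(m),
        positions = lapply(positions(m), paste, collapse = ""),
        instances = knownInstances(m))),
      provenance = db@provenance[!vapply(db@provenance, is.function,
                                         logical(1))])
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  tab <- data.frame(
    identifier = identifier(db),
    name = groupName(db),
    regex = vapply(motifClasses(db), sourceRegex, character(1)),
    instances = knownInstances(db),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# motifSpace class table", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readClassJson <- function(path, alphabet, symbolMap) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(payload$alphabet))
    alphabet <- unlist(payload$alphabet, use.names = FALSE)
  classes <- lapply(payload$classes, function(rec) {
    if (!is.null(rec$positions)) {
      pos <- lapply(rec$positions, function(p)
        strsplit(p, "", fixed = TRUE)[[1]])
      m <- motifFromPositions(pos, identifier = rec$identifier,
                              name = rec$name,
                              instances = rec$instances %||% 0L,
                              alphabet = alphabet)
      # keep the original source regex so a JSON round trip is lossless
      m@sourceRegex <- rec$regex %||% m@sourceRegex
      if (!is.null(rec$simplified)) m@regex <- rec$simplified
      m
    } else {
      MotifClass(rec$regex, identifier = rec$identifier, name = rec$name,
                 instances = rec$instances %||% 0L, alphabet = alphabet,
                 symbolMap = symbolMap)
    }
  })
  prov <- payload$provenance %||% list()
  prov$source <- path
  prov$format <- "json"
  MotifDatabase(classes, alphabet = alphabet, provenance = prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
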