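#' @include AllClasses.R
NULL

.parseError <- function(msg, offset) {
  stop(errorCondition(paste0(msg, " (offset ", offset, ")"),
                      class = c("motifParseError", "error", "condition")))
}

# Tokenise a simplified ELM-style regex into position tokens. Each token is a
# list(text, set, nOpen, nClose): `text` is the surface form with the symbol
# map applied, `set` the allowed amino acids in alphabet order, and
# nOpen/nClose count capture parentheses attached to the token (groups are
# semantically transparent but preserved in the surface form).
.tokenizeRegex <- function(regex, alphabet, symbolMap = c(U = "C")) {
  if (length(regex) != 1L || is.na(regex))
    stop("'regex' must be a single string")
  chars <- strsplit(regex, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- list()
  pendingOpen <- 0L
  depth <- 0L

  mapSym <- function(ch, off) {
    if (length(symbolMap) && ch %in% names(symbolMap))
      ch <- unname(symbolMap[[ch]])
    if (!ch %in% alphabet)
      .parseError(paste0("symbol '", ch,
                         "' not in alphabet and not in symbol map"), off)
    ch
  }
  addToken <- function(text, set) {
    tokens[[length(tokens) + 1L]] <<- list(text = text, set = set,
                                           nOpen = pendingOpen, nClose = 0L)
    pendingOpen <<- 0L
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      pendingOpen <- pendingOpen + 1L
      depth <- depth + 1L
      i <- i + 1L
    } else if (ch == ")") {
      if (depth == 0L || length(tokens) == 0L)
        .parseError("unbalanced ')'", i)
      depth <- depth - 1L
      tokens[[length(tokens)]]$nClose <- tokens[[length(tokens)]]$nClose + 1L
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .parseError("unterminated character class '['", i)
      content <- if (j > i + 1L) chars[(i + 1L):(j - 1L)] else character()
      negate <- length(content) > 0L && content[1L] == "^"
      if (negate) content <- content[-1L]
      if (length(content) == 0L) .parseError("empty character class", i)
      bad <- content[!grepl("^[A-Za-z]$", content)]
      if (length(bad))
        .parseError(paste0("unsupported character '", bad[1L],
                           "' inside character class"), i)
      syms <- unique(vapply(content, mapSym, character(1), off = i))
      set <- if (negate) setdiff(alphabet, syms) else
        alphabet[alphabet %in% syms]
      if (length(set) == 0L)
        .parseError("character class excludes every alphabet symbol", i)
      text <- if (negate) paste0("[^", paste(syms, collapse = ""), "]") else
        paste0("[", paste(syms, collapse = ""), "]")
      addToken(text, set)
      i <- j + 1L
    } else if (ch == ".") {
      addToken(".", alphabet)
      i <- i + 1L
    } else if (ch %in% c("^", "$")) {
      .parseError(paste0("anchor '", ch,
                         "' must be removed by preprocessRegex()"), i)
    } else if (ch %in% c("|", "*", "+", "?")) {
      .parseError(paste0("unsupported construct '", ch, "'"), i)
    } else if (ch == "{") {
      j <- i + 1L
      while (j <= n && chars[j] != "}") j <- j + 1L
      if (j > n) .parseError("unterminated repetition '{'", i)
      spec <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (grepl(",", spec, fixed = TRUE))
        .parseError(paste0("bounded repetition {", spec,
                           "} must be reduced by preprocessRegex()"), i)
      if (!grepl("^[0-9]+$", spec))
        .parseError(paste0("malformed repetition {", spec, "}"), i)
      m <- as.integer(spec)
      if (length(tokens) == 0L)
        .parseError("repetition with no preceding position", i)
      last <- tokens[[length(tokens)]]
      if (last$nClose > 0L)
        .parseError("repetition of a parenthesised group is unsupported", i)
      if (m == 0L) {
        tokens[[length(tokens)]] <- NULL
      } else if (m > 1L) {
        for (r in seq_len(m - 1L))
          tokens[[length(tokens) + 1L]] <-
            list(text = last$text, set = last$set, nOpen = 0L, nClose = 0L)
      }
      i <- j + 1L
    } else if (grepl("^[A-Za-z]$", ch)) {
      s <- mapSym(ch, i)
      addToken(s, s)
      i <- i + 1L
    } else {
      .parseError(paste0("unexpected character '", ch, "'"), i)
    }
  }
  if (depth != 0L) .parseError("unbalanced '('", n)
  tokens
}

# Reassemble tokens into a regex string, keeping capture parentheses when they
# are still balanced after trimming, dropping them all otherwise (groups are
# semantically transparent either way).
.reassembleTokens <- function(tokens) {
  opens <- vapply(tokens, `[[`, integer(1), "nOpen")
  closes <- vapply(tokens, `[[`, integer(1), "nClose")
  balanced <- sum(opens) == sum(closes) &&
    all(cumsum(opens) >= cumsum(closes))
  texts <- vapply(tokens, `[[`, character(1), "text")
  if (balanced)
    paste0(strrep("(", opens), texts, strrep(")", closes), collapse = "")
  else
    paste0(texts, collapse = "")
}

#' Parse a simplified motif regular expression into allowed-amino-acid sets
#'
#' Expands a regular expression in the simplified ELM dialect into the ordered
#' list of allowed-symbol sets defining a linear motif class. The dialect
#' comprises literal symbols, bracketed classes `[XY...]`, negated classes
#' `[^X...]`, the wildcard `.` (full alphabet), transparent capture
#' parentheses, and fixed repetition `X{m}` (expanded in place). Anchors and
#' bounded repetitions `{m,n}` must have been removed by [preprocessRegex()]
#' first; alternation `|` and unbounded repetition `*`/`+` are rejected with
#' an error naming the construct and its offset.
#'
#' @inheritParams MotifClass
#' @return List of character vectors, one allowed set per motif position, in
#'   alphabet order.
#' @examples
#' str(parseMotifRegex("[LI].C.[DE]"))   # structure (2,20,1,20,2)
#' parseMotifRegex("[^P]")[[1]]          # the 19 residues other than P
#' @export
parseMotifRegex <- function(regex, alphabet = motifAlphabet(),
                            symbolMap = c(U = "C")) {
  .checkAlphabet(alphabet)
  tokens <- .tokenizeRegex(regex, alphabet, symbolMap)
  if (length(tokens) == 0L)
    stop("regex describes no motif position")
  lapply(tokens, `[[`, "set")
}

# find the start index of the single token (literal, '.', bracket class or
# parenthesised group) ending at position `end` of string `s`
.precedingTokenStart <- function(s, end) {
  ch <- substr(s, end, end)
  if (ch == "]") {
    k <- end
    while (k >= 1L && substr(s, k, k) != "[") k <- k - 1L
    if (k < 1L) .parseError("unmatched ']'", end)
    # include a wrapping '(' handled by the ')' branch only
    k
  } else if (ch == ")") {
    k <- end
    bal <- 0L
    while (k >= 1L) {
      c2 <- substr(s, k, k)
      if (c2 == ")") bal <- bal + 1L
      if (c2 == "(") {
        bal <- bal - 1L
        if (bal == 0L) return(k)
      }
      k <- k - 1L
    }
    .parseError("unmatched ')'", end)
  } else {
    end
  }
}

#' Preprocess a raw ELM-style regular expression
#'
#' Applies, in order, the four simplification rules used to curate motif
#' regular expressions before analysis:
#' \enumerate{
#'   \item Variable-length repetitions `{p,q}` are replaced by their shortest
#'     version `{p}`; `{0,q}` deletes the repeated token altogether.
#'   \item Terminal anchors `^` and `$` are stripped.
#'   \item Non-canonical residue letters are rewritten via `symbolMap`
#'     (default: selenocysteine `U` to `C`).
#'   \item Flanking positions are removed iteratively from both ends while
#'     the terminal position allows eleven or more amino acids; positions
#'     allowing at most ten are never trimmed.
#' }
#' The function is idempotent: preprocessing an already-simplified expression
#' returns it unchanged.
#'
#' @inheritParams MotifClass
#' @param wildcardMin Minimum allowed-set size at which a terminal position is
#'   considered non-specific and trimmed (default 11, i.e. positions allowing
#'   fewer than eleven residues are kept).
#' @return A list with elements `regex` (the simplified expression) and `log`
#'   (character vector describing each rule applied, with 1-based positions).
#' @examples
#' preprocessRegex("[LIVMP].{0,2}(T)P..([ST])")$regex  # "[LIVMP](T)P..([ST])"
#' preprocessRegex("F..F$")$regex                      # "F..F"
#' preprocessRegex("[KR]R.")$regex                     # "[KR]R"
#' preprocessRegex("RV.PU")$regex                      # "RV.PC"
#' @export
preprocessRegex <- function(regex, alphabet = motifAlphabet(),
                            symbolMap = c(U = "C"), wildcardMin = 11) {
  .checkAlphabet(alphabet)
  if (length(regex) != 1L || is.na(regex))
    stop("'regex' must be a single string")
  r <- regex
  log <- character()

  # 1. variable-length repetitions -> shortest version
  repeat {
    m <- regexpr("\\{([0-9]+),([0-9]+)\\}", r)
    if (m < 0L) break
    start <- as.integer(m)
    end <- start + attr(m, "match.length") - 1L
    spec <- substr(r, start + 1L, end - 1L)
    p <- as.integer(strsplit(spec, ",", fixed = TRUE)[[1]][1])
    if (p == 0L) {
      ts <- .precedingTokenStart(r, start - 1L)
      r <- paste0(substr(r, 1L, ts - 1L), substring(r, end + 1L))
      log <- c(log, paste0("repetition {", spec,
                           "}: dropped optional token at position ", ts))
    } else {
      rep <- if (p == 1L) "" else paste0("{", p, "}")
      r <- paste0(substr(r, 1L, start - 1L), rep, substring(r, end + 1L))
      log <- c(log, paste0("repetition {", spec, "} reduced to shortest ({",
                           p, "})"))
    }
  }

  # 2. terminal anchors
  if (startsWith(r, "^")) {
    r <- substring(r, 2L)
    log <- c(log, "stripped N-terminal anchor '^'")
  }
  if (endsWith(r, "$") ) {
    r <- substr(r, 1L, nchar(r) - 1L)
    log <- c(log, "stripped C-terminal anchor '$'")
  }

  # 3. symbol map rewrites (textual, so the log reflects the raw expression)
  for (from in names(symbolMap)) {
    if (grepl(from, r, fixed = TRUE)) {
      r <- gsub(from, symbolMap[[from]], r, fixed = TRUE)
      log <- c(log, paste0("mapped modified residue '", from, "' to '",
                           symbolMap[[from]], "'"))
    }
  }

  # 4. trim non-specific flanks (needs tokenisation to know set sizes)
  tokens <- .tokenizeRegex(r, alphabet, symbolMap)
  while (length(tokens) > 0L &&
         length(tokens[[1L]]$set) >= wildcardMin) {
    log <- c(log, paste0("trimmed leading position allowing ",
                         length(tokens[[1L]]$set), " residues"))
    tokens <- tokens[-1L]
  }
  while (length(tokens) > 0L &&
         length(tokens[[length(tokens)]]$set) >= wildcardMin) {
    log <- c(log, paste0("trimmed trailing position allowing ",
                         length(tokens[[length(tokens)]]$set), " residues"))
    tokens <- tokens[-length(tokens)]
  }
  if (length(tokens) == 0L)
    stop("motif fully wildcard: no position allowing fewer than ",
         wildcardMin, " residues remains in '", regex, "'")

  list(regex = .reassembleTokens(tokens), log = log)
}

#' Canonical regular expression for a list of position sets
#'
#' Emits the canonical surface form of a motif class: a literal symbol for
#' singleton sets, `.` for the full alphabet, and a bracketed class (symbols
#' in alphabet order) otherwise. `parseMotifRegex(canonicalRegex(p)) == p`
#' for any valid position list.
#'
#' @param positions List of character vectors (allowed sets) or a
#'   [MotifClass].
#' @inheritParams MotifClass
#' @return Character scalar.
#' @examples
#' canonicalRegex(list(c("L", "I"), motifAlphabet(), "C"))
#' @export
canonicalRegex <- function(positions, alphabet = motifAlphabet()) {
  if (is(positions, "MotifClass")) {
    alphabet <- alphabet(positions)
    positions <- positions(positions)
  }
  .checkAlphabet(alphabet)
  vapply(positions, function(p) {
    p <- alphabet[alphabet %in% p]
    if (length(p) == 0L) stop("empty position set")
    if (length(p) == length(alphabet)) "." else
      if (length(p) == 1L) p else paste0("[", paste(p, collapse = ""), "]")
  }, character(1)) |> paste0(collapse = "")
}
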