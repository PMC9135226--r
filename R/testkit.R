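# Specification testing: execution of embedded testdata sections, and
# automatic generation of valid/invalid examples for every datatype.

asTestdataTrees <- function(tests, spec) {
  if (is.null(tests)) return(spec@testdata)
  if (inherits(tests, "TestData")) {
    tree <- list(
      valid = structure(lapply(tests$valid, `[[`, "value"),
                        names = vapply(tests$valid, `[[`, character(1L),
                                       "text")),
      invalid = list(encoded = as.list(tests$invalid_encoded),
                     decoded = tests$invalid_decoded))
    out <- list(tree)
    names(out) <- attr(tests, "datatype")
    return(out)
  }
  if (is.character(tests)) return(parseSpecSource(tests)$testdata)
  if (is.list(tests)) return(tests)
  tfError("flatformatsUsageError", "unsupported testdata input")
}

#' Run the test data of a specification
#'
#' For every valid (text, value) pair: asserts that decoding the text gives
#' the value and that encoding the value yields text that decodes back to
#' it.  For every invalid encoded example: asserts that validation rejects
#' it.  For every invalid decoded example: asserts that encoding fails.
#'
#' @param spec a [CompiledSpecification-class].
#' @param tests test data: `NULL` to use the testdata section embedded in
#'   the specification, a path/text of a document with a `testdata`
#'   section, a testdata tree (named list datatype -> cases with keys
#'   `valid` -- mapping text to expected value, or plain list of texts --
#'   and `invalid` -- plain list of texts or mapping with keys `encoded`
#'   and `decoded`), or a `TestData` object from [generateExamples()].
#' @return a [TestReport-class].
#' @export
runTestdata <- function(spec, tests = NULL) {
  stopifnot(methods::is(spec, "CompiledSpecification"))
  trees <- asTestdataTrees(tests, spec)
  ctx <- makeCtx(spec)
  passed <- 0L
  fails <- list()
  fail <- function(datatype, direction, case, detail) {
    fails[[length(fails) + 1L]] <<- data.frame(
      datatype = datatype, direction = direction, case = case,
      detail = detail, stringsAsFactors = FALSE)
  }
  for (name in names(trees)) {
    if (!name %in% names(spec@table))
      tfError("flatformatsUnknownDatatype",
              sprintf("testdata references unknown datatype '%s'", name))
    def <- spec@table[[name]]
    node <- trees[[name]]
    valid <- node[["valid"]] %||% list()
    vnames <- names(valid)
    for (i in seq_along(valid)) {
      hasValue <- !is.null(vnames)
      text <- if (hasValue) vnames[i] else valid[[i]]
      obs <- tryCatch(list(ok = tfDecode(text, def, ctx)),
                      flatformatsDecodeError = function(e) e)
      if (inherits(obs, "error")) {
        fail(name, "decode", text, conditionMessage(obs))
        next
      }
      value <- if (hasValue) valid[[i]] else obs$ok
      if (hasValue && !dvEqual(obs$ok, value)) {
        fail(name, "decode", text,
             sprintf("decoded to %s, expected %s", dvKey(obs$ok),
                     dvKey(value)))
        next
      }
      reenc <- tryCatch(list(ok = tfEncode(value, def, ctx)),
                        flatformatsEncodeError = function(e) e)
      if (inherits(reenc, "error")) {
        fail(name, "encode", text, conditionMessage(reenc))
        next
      }
      redec <- tryCatch(list(ok = tfDecode(reenc$ok, def, ctx)),
                        flatformatsDecodeError = function(e) e)
      if (inherits(redec, "error") || !dvEqual(redec$ok, value)) {
        fail(name, "encode", text, sprintf(
          "encoding gave '%s' which does not decode back to the value",
          reenc$ok))
        next
      }
      passed <- passed + 1L
    }
    invalid <- node[["invalid"]] %||% list()
    invEnc <- if (is.list(invalid) && !is.null(names(invalid)))
      invalid[["encoded"]] %||% list() else invalid
    invDec <- if (is.list(invalid) && !is.null(names(invalid)))
      invalid[["decoded"]] %||% list() else list()
    for (text in invEnc) {
      if (tfIsValidEncoded(as.character(text), def, ctx,
                           spec@matchers[[name]]))
        fail(name, "validate-encoded", as.character(text),
             "expected invalid, but validation accepts it")
      else passed <- passed + 1L
    }
    for (i in seq_along(invDec)) {
      v <- invDec[[i]]
      if (tfIsValidDecoded(v, def, ctx))
        fail(name, "validate-decoded", dvKey(v),
             "expected unrepresentable, but encoding succeeds")
      else passed <- passed + 1L
    }
  }
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(datatype = character(0L), direction = character(0L),
               case = character(0L), detail = character(0L),
               stringsAsFactors = FALSE)
  methods::new("TestReport", passed = passed, failed = nrow(failures),
               failures = failures)
}

# ---------------------------------------------------------------------------
# regex-directed synthesis of example strings

CHAR_POOL <- c(LETTERS, letters, as.character(0:9),
               c("_", ".", ":", "-", "+", "|", " ", "#", "/"))

parseRegexAst <- function(pattern) {
  chars <- strsplit(pattern, "")[[1L]]
  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[[pos]] else NA_character_
  advance <- function() { c <- peek(); pos <<- pos + 1L; c }
  unsupported <- function(what)
    tfError("flatformatsUnsatisfiable",
            sprintf("cannot synthesize examples from pattern '%s': %s",
                    pattern, what))

  parseAlternation <- function() {
    branches <- list(parseSequence())
    while (identical(peek(), "|")) {
      advance()
      branches[[length(branches) + 1L]] <- parseSequence()
    }
    list(type = "alt", branches = branches)
  }
  parseSequence <- function() {
    items <- list()
    while (!is.na(peek()) && !peek() %in% c("|", ")")) {
      atom <- parseAtom()
      q <- parseQuantifier()
      items[[length(items) + 1L]] <-
        if (is.null(q)) atom else list(type = "rep", node = atom,
                                       min = q$min, max = q$max)
    }
    list(type = "seq", items = items)
  }
  parseQuantifier <- function() {
    c <- peek()
    if (is.na(c)) return(NULL)
    if (c == "?") { advance(); return(list(min = 0L, max = 1L)) }
    if (c == "*") { advance(); return(list(min = 0L, max = NA_integer_)) }
    if (c == "+") { advance(); return(list(min = 1L, max = NA_integer_)) }
    if (c == "{") {
      j <- pos + 1L
      digits1 <- character(0L); digits2 <- character(0L)
      comma <- FALSE
      while (j <= length(chars) && chars[[j]] != "}") {
        if (chars[[j]] == ",") comma <- TRUE
        else if (comma) digits2 <- c(digits2, chars[[j]])
        else digits1 <- c(digits1, chars[[j]])
        j <- j + 1L
      }
      if (j > length(chars)) unsupported("unterminated {")
      pos <<- j + 1L
      m <- as.integer(paste(digits1, collapse = ""))
      M <- if (!comma) m else if (length(digits2))
        as.integer(paste(digits2, collapse = "")) else NA_integer_
      return(list(min = m, max = M))
    }
    NULL
  }
  parseAtom <- function() {
    c <- advance()
    if (is.na(c)) unsupported("unexpected end")
    if (c == "(") {
      if (identical(peek(), "?")) {
        advance()
        nxt <- peek()
        if (identical(nxt, ":")) advance()
        else if (identical(nxt, "<") ) {
          # named group (?<name>...)
          advance()
          if (peek() %in% c("=", "!")) unsupported("lookbehind")
          while (!is.na(peek()) && peek() != ">") advance()
          advance()
        } else unsupported("lookaround or inline flags")
      }
      node <- parseAlternation()
      if (!identical(advance(), ")")) unsupported("unbalanced group")
      return(node)
    }
    if (c == "[") return(parseClass())
    if (c == "\\") return(parseEscape(advance()))
    if (c == ".") return(list(type = "class", chars = CHAR_POOL))
    if (c %in% c("^", "$")) return(list(type = "seq", items = list()))
    if (c %in% c("*", "+", "?", "{", "}")) unsupported(
      sprintf("dangling quantifier '%s'", c))
    list(type = "lit", char = c)
  }
  escapeChars <- function(c) {
    switch(c,
           d = as.character(0:9),
           D = setdiff(CHAR_POOL, as.character(0:9)),
           w = c(LETTERS, letters, as.character(0:9), "_"),
           W = setdiff(CHAR_POOL, c(LETTERS, letters, as.character(0:9), "_")),
           s = c(" ", "\t"),
           S = setdiff(CHAR_POOL, c(" ", "\t")),
           t = "\t",
           n = "\n",
           r = "\r",
           NULL)
  }
  parseEscape <- function(c) {
    if (is.na(c)) unsupported("trailing backslash")
    ec <- escapeChars(c)
    if (!is.null(ec)) return(list(type = "class", chars = ec))
    if (grepl("[0-9]", c)) unsupported("backreference")
    list(type = "lit", char = c)
  }
  parseClass <- function() {
    negated <- FALSE
    if (identical(peek(), "^")) { negated <- TRUE; advance() }
    members <- character(0L)
    first <- TRUE
    while (!is.na(peek()) && (peek() != "]" || first)) {
      first <- FALSE
      c <- advance()
      if (c == "\\") {
        e <- advance()
        ec <- escapeChars(e)
        if (!is.null(ec)) { members <- c(members, ec); next }
        c <- e
      }
      if (identical(peek(), "-") && pos + 1L <= length(chars) &&
          chars[[pos + 1L]] != "]") {
        advance()
        hi <- advance()
        if (hi == "\\") hi <- advance()
        rng <- tryCatch(
          vapply(utf8ToInt(c):utf8ToInt(hi), intToUtf8, character(1L)),
          error = function(e) unsupported("bad class range"))
        members <- c(members, rng)
      } else members <- c(members, c)
    }
    if (!identical(advance(), "]")) unsupported("unterminated class")
    chars_ <- if (negated) setdiff(CHAR_POOL, members) else unique(members)
    if (!length(chars_)) unsupported("empty character class")
    list(type = "class", chars = chars_)
  }

  ast <- parseAlternation()
  if (pos <= length(chars)) unsupported("unbalanced pattern")
  ast
}

generateFromAst <- function(node, repCap = 3L) {
  switch(node$type,
    alt = {
      b <- node$branches[[sample.int(length(node$branches), 1L)]]
      generateFromAst(b, repCap)
    },
    seq = paste(vapply(node$items, generateFromAst, character(1L),
                       repCap = repCap), collapse = ""),
    rep = {
      m <- node$min
      M <- if (is.na(node$max)) m + repCap else min(node$max, m + repCap)
      k <- if (M > m) m + sample.int(M - m + 1L, 1L) - 1L else m
      paste(vapply(seq_len(k), function(i) generateFromAst(node$node, repCap),
                   character(1L)), collapse = "")
    },
    class = node$chars[[sample.int(length(node$chars), 1L)]],
    lit = node$char)
}

# One string matching `pattern` (bounded repetition keeps examples short).
synthesizeFromRegex <- function(pattern) {
  ast <- parseRegexAst(pattern)
  for (i in 1:25) {
    s <- generateFromAst(ast)
    if (fullMatch(pattern, s)) return(s)
  }
  tfError("flatformatsUnsatisfiable",
          sprintf("failed to synthesize a string matching '%s'", pattern))
}

# ---------------------------------------------------------------------------
# example generation per definition kind

boundedInterval <- function(p, integerOnly = TRUE) {
  lo <- p$min; hi <- p$max
  if (!is.finite(lo)) lo <- min(-1000, if (is.finite(hi)) hi - 1000 else 0)
  if (!is.finite(hi)) hi <- max(1000, lo + 1000)
  c(lo, hi)
}

genOneText <- function(def, ctx) {
  def <- resolveDef(def, ctx$table)
  p <- def@params
  r <- def@rules
  core <- switch(def@kind,
    constant = p$text,
    values = p$texts[[sample.int(length(p$texts), 1L)]],
    regex = synthesizeFromRegex(p$pattern),
    regexes = synthesizeFromRegex(
      p$patterns[[sample.int(length(p$patterns), 1L)]]),
    integer = {
      b <- boundedInterval(p)
      formatInt(floor(b[1L] + (b[2L] - b[1L]) * runif(1L)))
    },
    unsigned_integer = {
      b <- boundedInterval(p)
      formatBase(floor(b[1L] + (b[2L] - b[1L]) * runif(1L)), p$base)
    },
    float = {
      b <- boundedInterval(p, FALSE)
      v <- b[1L] + (b[2L] - b[1L]) * runif(1L)
      if ((p$minExcluded && v <= p$min) || (p$maxExcluded && v >= p$max))
        v <- (b[1L] + b[2L]) / 2
      formatFloat(v)
    },
    list_of = {
      len <- if (!is.na(p$length)) p$length else {
        hi <- if (!is.na(p$maxLength)) min(p$maxLength, p$minLength + 2L)
        else p$minLength + 2L
        p$minLength + sample.int(hi - p$minLength + 1L, 1L) - 1L
      }
      if (len == 0L) "" else
        paste(vapply(seq_len(len), function(i) genOneText(p$element, ctx),
                     character(1L)), collapse = p$separator)
    },
    labeled_list = {
      optional <- setdiff(names(p$labels), p$required)
      chosen <- c(p$required,
                  optional[runif(length(optional)) < 0.5])
      if (!length(chosen)) chosen <- names(p$labels)[[1L]]
      chosen <- names(p$labels)[names(p$labels) %in% chosen]  # listed order
      paste(vapply(chosen, function(lab)
        paste0(lab, p$internalSeparator, genOneText(p$labels[[lab]], ctx)),
        character(1L)), collapse = p$separator)
    },
    tagged_list = {
      k <- sample.int(2L, 1L)
      nms <- character(0L)
      for (i in seq_len(k)) {
        for (try in 1:10) {
          nm <- synthesizeFromRegex(p$namePattern)
          if (!nm %in% nms) { nms <- c(nms, nm); break }
        }
      }
      paste(vapply(nms, function(nm) {
        code <- names(p$codes)[[sample.int(length(p$codes), 1L)]]
        paste0(nm, p$internalSeparator, code, p$internalSeparator,
               genOneText(p$codes[[code]], ctx))
      }, character(1L)), collapse = p$separator)
    },
    composed_of = {
      n <- length(p$fields)
      npresent <- p$nRequired +
        sample.int(n - p$nRequired + 1L, 1L) - 1L
      if (npresent == 0L) "" else
        paste(vapply(seq_len(npresent), function(i)
          genOneText(p$fields[[i]], ctx), character(1L)),
          collapse = p$separator)
    },
    one_of = genOneText(
      p$alternatives[[sample.int(length(p$alternatives), 1L)]], ctx))
  paste0(r$prefix %||% "", core, r$suffix %||% "")
}

# kind-specific "coverage" examples generated first: boundaries of
# intervals, every member of a value set, one example per alternative
coverageTexts <- function(def, ctx) {
  def <- resolveDef(def, ctx$table)
  p <- def@params
  r <- def@rules
  wrap <- function(x) paste0(r$prefix %||% "", x, r$suffix %||% "")
  out <- switch(def@kind,
    constant = wrap(p$text),
    values = wrap(p$texts),
    integer = wrap(c(if (is.finite(p$min)) formatInt(p$min),
                     if (is.finite(p$max)) formatInt(p$max))),
    unsigned_integer = wrap(c(
      if (is.finite(p$min)) formatBase(p$min, p$base),
      if (is.finite(p$max)) formatBase(p$max, p$base))),
    float = wrap(c(
      if (is.finite(p$min) && !p$minExcluded) formatFloat(p$min),
      if (is.finite(p$max) && !p$maxExcluded) formatFloat(p$max))),
    one_of = unlist(lapply(p$alternatives, function(a)
      tryCatch(genOneText(a, ctx),
               flatformatsUnsatisfiable = function(e) NULL))),
    character(0L))
  if (!is.null(r$empty)) out <- c(out, "")
  out
}

invalidCandidates <- function(def, ctx, validTexts) {
  def <- resolveDef(def, ctx$table)
  p <- def@params
  r <- def@rules
  # boundary violations first, then member/text mutations
  out <- c(switch(def@kind,
    integer = c(if (is.finite(p$min)) formatInt(p$min - 1),
                if (is.finite(p$max)) formatInt(p$max + 1), "x", "1.5"),
    unsigned_integer = c(
      if (is.finite(p$min) && p$min > 0) formatBase(p$min - 1, p$base),
      if (is.finite(p$max)) formatBase(p$max + 1, p$base), "-1", "G"),
    float = c(if (is.finite(p$min))
      formatFloat(p$min - 1),
      if (is.finite(p$max)) formatFloat(p$max + 1),
      if (p$minExcluded && is.finite(p$min)) formatFloat(p$min),
      if (p$maxExcluded && is.finite(p$max)) formatFloat(p$max), "x"),
    values = paste0(p$texts, "~X"),
    constant = paste0(p$text, "~X"),
    character(0L)))
  mut <- function(t) c(paste0(t, "~"), paste0("~", t),
                       substr(t, 1L, nchar(t) - 1L),
                       substring(t, 2L))
  for (t in validTexts[seq_len(min(5L, length(validTexts)))])
    out <- c(out, mut(t))
  sepCorrupt <- function(t, sep) {
    if (nzchar(sep) && grepl(sep, t, fixed = TRUE))
      gsub(sep, "\x01", t, fixed = TRUE)
  }
  if (def@kind %in% c("list_of", "labeled_list", "tagged_list",
                      "composed_of"))
    for (t in validTexts[seq_len(min(3L, length(validTexts)))])
      out <- c(out, sepCorrupt(t, p$separator))
  if (!is.null(r$prefix))
    for (t in validTexts[seq_len(min(3L, length(validTexts)))])
      out <- c(out, substring(t, nchar(r$prefix) + 1L))
  # non-printable / whitespace probes for otherwise permissive patterns
  out <- c(out, "\x01", " ", "\t",
           paste0("\x01", if (length(validTexts)) validTexts[[1L]] else ""))
  unique(out)
}

invalidDecodedCandidates <- function(def, ctx) {
  def <- resolveDef(def, ctx$table)
  p <- def@params
  cands <- list("~not~a~value~", list(unexpected_field = "~"))
  if (def@kind %in% c("integer", "unsigned_integer", "float")) {
    if (is.finite(p$min)) cands <- c(cands, list(p$min - 1))
    if (is.finite(p$max)) cands <- c(cands, list(p$max + 1))
  }
  cands
}

#' Generate valid and invalid examples for a datatype
#'
#' Valid examples are built constructively per kind (a constant yields its
#' text; value sets their members; intervals boundary and interior points;
#' compounds by recursive composition; regex kinds by pattern-directed
#' synthesis with bounded repetition).  Invalid examples are produced by
#' boundary violation, member mutation, separator corruption and prefix
#' removal, and are verified to fail validation.  Generation is
#' deterministic given `seed`.
#'
#' @param spec a [CompiledSpecification-class] (or a standalone
#'   [DatatypeDefinition-class], in which case `datatype` is ignored).
#' @param datatype name of the datatype to generate for.
#' @param nValid,nInvalid number of valid/invalid examples requested.
#' @param seed integer seed.
#' @return an object of class `TestData`: a list with elements `valid`
#'   (list of `list(text=, value=)` pairs), `invalid_encoded` (character)
#'   and `invalid_decoded` (list); attribute `datatype` carries the name.
#' @examples
#' spec <- loadSpecification("datatypes: {n: {integer: {min: 0, max: 10}}}")
#' generateExamples(spec, "n", nValid = 3, nInvalid = 2, seed = 1)
#' @export
generateExamples <- function(spec, datatype = NULL, nValid = 5L,
                             nInvalid = 5L, seed = 0L) {
  if (methods::is(spec, "DatatypeDefinition")) {
    def <- spec
    ctx <- makeCtx(NULL)
    datatype <- def@name
  } else {
    def <- getDatatype(spec, datatype)
    ctx <- makeCtx(spec)
  }
  stopifnot(nValid >= 0L, nInvalid >= 0L)
  withSeed(seed, {
    texts <- coverageTexts(def, ctx)
    guard <- 0L
    while (length(texts) < nValid && guard < 50L * (nValid + 1L)) {
      texts <- c(texts, genOneText(def, ctx))
      guard <- guard + 1L
    }
    texts <- texts[seq_len(min(length(texts), max(nValid, length(texts))))]
    if (nValid > 0L && length(texts) > nValid)
      texts <- unique(texts)[seq_len(min(nValid, length(unique(texts))))]
    valid <- lapply(texts, function(t) {
      v <- tryCatch(list(ok = tfDecode(t, def, ctx)),
                    flatformatsDecodeError = function(e) NULL)
      if (is.null(v))
        tfError("flatformatsInternalError", sprintf(
          "generated example '%s' does not decode under '%s'", t, datatype))
      list(text = t, value = v$ok)
    })
    invalid <- character(0L)
    if (nInvalid > 0L) {
      cands <- invalidCandidates(def, ctx, texts)
      for (cand in cands) {
        if (length(invalid) >= nInvalid) break
        if (!tfIsValidEncoded(cand, def, ctx)) invalid <- c(invalid, cand)
      }
      if (!length(invalid))
        tfError("flatformatsUnsatisfiable", sprintf(
          "cannot construct invalid examples for '%s' (does it accept every string?)",
          datatype))
    }
    invDec <- Filter(function(v) !tfIsValidDecoded(v, def, ctx),
                     invalidDecodedCandidates(def, ctx))
    invDec <- invDec[seq_len(min(length(invDec), nInvalid))]
    structure(list(valid = valid, invalid_encoded = invalid,
                   invalid_decoded = invDec),
              class = "TestData", datatype = datatype)
  })
}

#' @export
print.TestData <- function(x, ...) {
  cat(sprintf("TestData for '%s': %d valid, %d invalid encoded, %d invalid decoded\n",
              attr(x, "datatype"), length(x$valid),
              length(x$invalid_encoded), length(x$invalid_decoded)))
  invisible(x)
}
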