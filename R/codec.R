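# Core operations: decode, encode, validate (encoded / decoded side), on
# single strings and on files with line / unit / section / file scopes.

makeCtx <- function(spec) {
  if (methods::is(spec, "CompiledSpecification"))
    list(table = spec@table, cache = spec@cache)
  else list(table = list(), cache = new.env(parent = emptyenv()))
}

applyDecodedMap <- function(text, rules) {
  dec <- rules$decoded
  if (!is.null(dec) && text %in% names(dec)) return(dec[[text]])
  text
}

# ---------------------------------------------------------------------------
# decode

tfDecode <- function(text, def, ctx, path = character(0L), off = 1L) {
  def <- resolveDef(def, ctx$table)
  p <- def@params
  r <- def@rules
  if (!is.null(r$empty) && !nzchar(text)) return(r$empty$value)
  if (!is.null(r$prefix)) {
    if (!startsWith(text, r$prefix))
      decodeError(sprintf("expected prefix '%s'", r$prefix), path, off)
    text <- substring(text, nchar(r$prefix) + 1L)
    off <- off + nchar(r$prefix)
  }
  if (!is.null(r$suffix)) {
    if (!endsWith(text, r$suffix))
      decodeError(sprintf("expected suffix '%s'", r$suffix), path,
                  off + nchar(text))
    text <- substring(text, 1L, nchar(text) - nchar(r$suffix))
  }
  if (!is.null(r$must_match) && !fullMatch(r$must_match, text))
    decodeError(sprintf("text does not satisfy pattern '%s'", r$must_match),
                path, off)

  switch(def@kind,
    constant = {
      if (text != p$text)
        decodeError(sprintf("expected constant '%s', found '%s'",
                            p$text, text), path, off)
      p$value
    },
    values = {
      if (!text %in% p$texts)
        decodeError(sprintf("'%s' is not one of the permitted values (%s)",
                            text, paste(p$texts, collapse = ", ")),
                    path, off)
      applyDecodedMap(text, r)
    },
    regex = {
      if (!fullMatch(p$pattern, text))
        decodeError(sprintf("'%s' does not match pattern '%s'",
                            text, p$pattern), path, off)
      applyDecodedMap(text, r)
    },
    regexes = {
      hit <- FALSE
      for (pat in p$patterns) if (fullMatch(pat, text)) { hit <- TRUE; break }
      if (!hit)
        decodeError(sprintf("'%s' matches none of the %d patterns",
                            text, length(p$patterns)), path, off)
      applyDecodedMap(text, r)
    },
    integer = {
      if (!fullMatch("[+-]?[0-9]+", text))
        decodeError(sprintf("'%s' is not a base-10 integer", text), path, off)
      v <- as.numeric(text)
      if (v < p$min || v > p$max)
        decodeError(sprintf("%s out of interval [%s, %s]", text,
                            p$min, p$max), path, off)
      if (abs(v) <= .Machine$integer.max) as.integer(v) else v
    },
    unsigned_integer = {
      digits <- switch(as.character(p$base), "2" = "[01]", "8" = "[0-7]",
                       "10" = "[0-9]", "16" = "[0-9A-Fa-f]")
      pre <- switch(as.character(p$base), "2" = "(?:0[bB])?",
                    "8" = "(?:0[oO])?", "16" = "(?:0[xX])?", "")
      if (!fullMatch(paste0(pre, digits, "+"), text))
        decodeError(sprintf("'%s' is not a base-%d unsigned integer",
                            text, p$base), path, off)
      core <- sub("^0[bBoOxX]", "", text)
      if (p$base == 10L) core <- text
      v <- parseBase(core, p$base)
      if (v < p$min || v > p$max)
        decodeError(sprintf("%s out of interval [%s, %s]", text,
                            p$min, p$max), path, off)
      if (abs(v) <= .Machine$integer.max) as.integer(v) else v
    },
    float = {
      if (!fullMatch(
        "[+-]?(?:[0-9]+(?:\\.[0-9]*)?|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?", text))
        decodeError(sprintf("'%s' is not a floating point number", text),
                    path, off)
      v <- as.numeric(text)
      lo <- if (p$minExcluded) v > p$min else v >= p$min
      hi <- if (p$maxExcluded) v < p$max else v <= p$max
      if (!lo || !hi)
        decodeError(sprintf("%s out of interval %s%s, %s%s", text,
                            if (p$minExcluded) "(" else "[", p$min, p$max,
                            if (p$maxExcluded) ")" else "]"), path, off)
      v
    },
    list_of = decodeListOf(text, def, ctx, path, off),
    labeled_list = decodeLabeledList(text, def, ctx, path, off),
    tagged_list = decodeTaggedList(text, def, ctx, path, off),
    composed_of = decodeComposedOf(text, def, ctx, path, off),
    one_of = {
      for (i in seq_along(p$alternatives)) {
        v <- tryCatch(
          list(ok = tfDecode(text, p$alternatives[[i]], ctx,
                             c(path, sprintf("<%d>", i)), off)),
          flatformatsDecodeError = function(e) NULL)
        if (!is.null(v)) return(v$ok)
      }
      decodeError(sprintf("'%s' matches none of the %d alternatives",
                          text, length(p$alternatives)), path, off)
    })
}

checkListCount <- function(n, p, text, path, off) {
  if (!is.na(p$length) && n != p$length)
    decodeError(sprintf("expected exactly %d elements, found %d",
                        p$length, n), path, off)
  if (n < p$minLength)
    decodeError(sprintf("expected at least %d elements, found %d",
                        p$minLength, n), path, off)
  if (!is.na(p$maxLength) && n > p$maxLength)
    decodeError(sprintf("expected at most %d elements, found %d",
                        p$maxLength, n), path, off)
}

decodeListOf <- function(text, def, ctx, path, off) {
  p <- def@params
  if (!nzchar(text) &&
      (p$minLength == 0L || identical(p$length, 0L))) return(list())
  if (p$splitted) {
    parts <- splitKeep(text, p$separator)
    starts <- splitKeepStarts(text, p$separator)
  } else {
    pe <- peelParts(text, p$element, p$separator, ctx, path, off)
    parts <- pe$parts; starts <- pe$starts
  }
  checkListCount(length(parts), p, text, path, off)
  out <- vector("list", length(parts))
  for (i in seq_along(parts))
    out[i] <- list(tfDecode(parts[[i]], p$element, ctx,
                            c(path, sprintf("[%d]", i)),
                            off + starts[[i]] - 1L))
  out
}

# Split `text` into parts separated by the literal (but non-exclusive)
# separator, using the element pattern with backtracking: repeatedly match
# ^(head)(sep (rest))?$ where head is one element.
peelParts <- function(text, elemDef, sep, ctx, path, off) {
  eb <- bodyFor(elemDef, ctx$table, ctx$cache)$body
  S <- escapeRegex(sep)
  pat <- paste0("^(?<h>(?:", eb, "))(?:", S, "(?<t>.*))?$")
  parts <- character(0L); starts <- integer(0L)
  pos <- 1L
  remaining <- text
  repeat {
    m <- regexpr(pat, remaining, perl = TRUE)
    if (m == -1L)
      decodeError(sprintf("cannot parse list element near position %d", pos),
                  path, off + pos - 1L)
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    h <- substr(remaining, cs[1L, "h"], cs[1L, "h"] + cl[1L, "h"] - 1L)
    parts <- c(parts, h); starts <- c(starts, pos)
    tStart <- cs[1L, "t"]
    if (is.na(tStart) || tStart <= 0L) break
    consumed <- cl[1L, "h"] + nchar(sep)
    remaining <- substr(remaining, tStart, nchar(remaining))
    pos <- pos + consumed
    if (!nzchar(remaining)) { # trailing empty element
      parts <- c(parts, ""); starts <- c(starts, pos)
      break
    }
  }
  list(parts = parts, starts = starts)
}

splitFirst <- function(text, sep) {
  i <- regexpr(sep, text, fixed = TRUE)
  if (i == -1L) return(NULL)
  list(head = substr(text, 1L, i - 1L),
       tail = substring(text, i + nchar(sep)))
}

decodeLabeledList <- function(text, def, ctx, path, off) {
  p <- def@params
  if (p$splitted) {
    items <- splitKeep(text, p$separator)
    starts <- splitKeepStarts(text, p$separator)
  } else {
    # one item is label + internal separator + value; peel with a permissive
    # item pattern, then parse each item
    itemBody <- paste0("(?:",
      paste0(vapply(names(p$labels), function(lab) {
        b <- bodyFor(p$labels[[lab]], ctx$table, ctx$cache)$body
        paste0(escapeRegex(lab), escapeRegex(p$internalSeparator),
               "(?:", b, ")")
      }, character(1L)), collapse = "|"), ")")
    pe <- peelRaw(text, itemBody, p$separator, path, off)
    items <- pe$parts; starts <- pe$starts
  }
  out <- list()
  for (i in seq_along(items)) {
    ipath <- c(path, sprintf("[%d]", i))
    ioff <- off + starts[[i]] - 1L
    sp <- splitFirst(items[[i]], p$internalSeparator)
    if (is.null(sp))
      decodeError(sprintf("missing internal separator '%s' in '%s'",
                          p$internalSeparator, items[[i]]), ipath, ioff)
    if (!sp$head %in% names(p$labels))
      decodeError(sprintf("unknown label '%s'", sp$head), ipath, ioff)
    if (sp$head %in% names(out))
      decodeError(sprintf("duplicated label '%s'", sp$head), ipath, ioff)
    out[sp$head] <- list(tfDecode(sp$tail, p$labels[[sp$head]], ctx,
                                  c(path, sp$head),
                                  ioff + nchar(sp$head) +
                                    nchar(p$internalSeparator)))
  }
  missing <- setdiff(p$required, names(out))
  if (length(missing))
    decodeError(sprintf("missing required label(s): %s",
                        paste(missing, collapse = ", ")), path, off)
  out
}

peelRaw <- function(text, itemBody, sep, path, off) {
  S <- escapeRegex(sep)
  pat <- paste0("^(?<h>", itemBody, ")(?:", S, "(?<t>.*))?$")
  parts <- character(0L); starts <- integer(0L); pos <- 1L
  remaining <- text
  repeat {
    m <- regexpr(pat, remaining, perl = TRUE)
    if (m == -1L)
      decodeError(sprintf("cannot parse element near position %d", pos),
                  path, off + pos - 1L)
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    parts <- c(parts, substr(remaining, cs[1L, "h"],
                             cs[1L, "h"] + cl[1L, "h"] - 1L))
    starts <- c(starts, pos)
    tStart <- cs[1L, "t"]
    if (is.na(tStart) || tStart <= 0L) break
    pos <- pos + cl[1L, "h"] + nchar(sep)
    remaining <- substr(remaining, tStart, nchar(remaining))
  }
  list(parts = parts, starts = starts)
}

decodeTaggedList <- function(text, def, ctx, path, off) {
  p <- def@params
  if (p$splitted) {
    items <- splitKeep(text, p$separator)
    starts <- splitKeepStarts(text, p$separator)
  } else {
    I <- escapeRegex(p$internalSeparator)
    codeAlts <- paste0(vapply(names(p$codes), function(code) {
      b <- bodyFor(p$codes[[code]], ctx$table, ctx$cache)$body
      paste0(escapeRegex(code), I, "(?:", b, ")")
    }, character(1L)), collapse = "|")
    itemBody <- paste0("(?:", p$namePattern, ")", I, "(?:", codeAlts, ")")
    pe <- peelRaw(text, itemBody, p$separator, path, off)
    items <- pe$parts; starts <- pe$starts
  }
  out <- list()
  for (i in seq_along(items)) {
    ipath <- c(path, sprintf("[%d]", i))
    ioff <- off + starts[[i]] - 1L
    s1 <- splitFirst(items[[i]], p$internalSeparator)
    if (is.null(s1))
      decodeError(sprintf("tag without internal separator: '%s'",
                          items[[i]]), ipath, ioff)
    name <- s1$head
    if (!fullMatch(p$namePattern, name))
      decodeError(sprintf("invalid tag name '%s'", name), ipath, ioff)
    if (name %in% names(out))
      decodeError(sprintf("duplicated tag name '%s'", name), ipath, ioff)
    s2 <- splitFirst(s1$tail, p$internalSeparator)
    if (is.null(s2))
      decodeError(sprintf("tag '%s' lacks a type code", name), ipath, ioff)
    code <- s2$head
    if (!code %in% names(p$codes))
      decodeError(sprintf("unknown tag type code '%s' (valid: %s)", code,
                          paste(names(p$codes), collapse = ", ")),
                  ipath, ioff + nchar(name) + nchar(p$internalSeparator))
    out[name] <- list(tfDecode(s2$tail, p$codes[[code]], ctx, c(path, name),
                               ioff + nchar(name) + nchar(code) +
                                 2L * nchar(p$internalSeparator)))
  }
  out
}

# whether one separator-delimited part can extend a variable-length field:
# for list_of, the part must be a valid element; for labeled/tagged lists a
# single part is a valid one-item list iff it validates on its own
partMatchesListElement <- function(part, fdef, ctx) {
  if (fdef@kind == "list_of")
    tfIsValidEncoded(part, fdef@params$element, ctx)
  else tfIsValidEncoded(part, fdef, ctx)
}

isListKind <- function(def, table) {
  def <- resolveDef(def, table)
  def@kind %in% c("list_of", "labeled_list", "tagged_list")
}

listSeparator <- function(def, table) {
  def <- resolveDef(def, table)
  def@params$separator
}

decodeComposedOf <- function(text, def, ctx, path, off) {
  p <- def@params
  nf <- length(p$fields)
  fnames <- names(p$fields)
  if (!nzchar(text) && p$nRequired == 0L)
    return(structure(list(), names = character(0L)))
  if (p$splitted) {
    parts <- splitKeep(text, p$separator)
    starts <- splitKeepStarts(text, p$separator)
    out <- list()
    pi <- 1L  # next unconsumed part
    for (i in seq_len(nf)) {
      fdef <- resolveDef(p$fields[[i]], ctx$table)
      remaining <- length(parts) - pi + 1L
      if (isListKind(fdef, ctx$table) &&
          identical(fdef@params$separator, p$separator) &&
          isTRUE(fdef@params$splitted)) {
        # a variable-length field (tags, a section of lines, ...) using
        # the same delimiter: consume the maximal run of parts matching
        # its element, reserving parts for later required fields
        reserve <- if (i < nf)
          sum(seq(i + 1L, nf) <= p$nRequired) else 0L
        maxTake <- remaining - reserve
        lim <- if (fdef@kind == "list_of") {
          if (!is.na(fdef@params$length)) fdef@params$length
          else fdef@params$maxLength
        } else NA_integer_
        if (!is.na(lim)) maxTake <- min(maxTake, lim)
        take <- 0L
        while (take < maxTake &&
               partMatchesListElement(parts[[pi + take]], fdef, ctx))
          take <- take + 1L
        if (take == 0L && remaining - reserve == 1L &&
            pi <= length(parts) && !nzchar(parts[[pi]])) {
          # a single empty trailing part: the empty representation of
          # the list (symmetric with encoding an empty list)
          take <- 1L
        }
        if (take == 0L && i > p$nRequired) next
        joined <- if (take == 0L) "" else
          paste(parts[seq(pi, pi + take - 1L)], collapse = p$separator)
        out[fnames[i]] <- list(tfDecode(joined, p$fields[[i]], ctx,
                                        c(path, fnames[i]),
                                        off + starts[[pi]] - 1L))
        pi <- pi + take
      } else {
        if (remaining < 1L) {
          if (i <= p$nRequired)
            decodeError(sprintf("missing required field '%s'", fnames[i]),
                        path, off + nchar(text))
          next
        }
        out[fnames[i]] <- list(tfDecode(parts[[pi]], p$fields[[i]], ctx,
                                        c(path, fnames[i]),
                                        off + starts[[pi]] - 1L))
        pi <- pi + 1L
      }
    }
    if (pi <= length(parts))
      decodeError(sprintf("too many fields: expected at most %d", nf),
                  path, off + starts[[pi]] - 1L)
    out
  } else {
    pat <- composedGroupPattern(def, ctx$table, ctx$cache)
    m <- regexpr(pat, text, perl = TRUE)
    if (m == -1L)
      decodeError(sprintf("'%s' does not match the composition of fields %s",
                          text, paste(fnames, collapse = ", ")), path, off)
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    out <- list()
    for (i in seq_len(nf)) {
      g <- paste0("g", i)
      st <- cs[1L, g]
      if (is.na(st) || st <= 0L) {
        if (i <= p$nRequired && cl[1L, g] != 0L)
          decodeError(sprintf("missing required field '%s'", fnames[i]),
                      path, off)
        if (i <= p$nRequired) {
          # matched empty at an undetectable position: decode empty text
          out[fnames[i]] <- list(tfDecode("", p$fields[[i]], ctx,
                                          c(path, fnames[i]), off))
        }
        next
      }
      part <- substr(text, st, st + cl[1L, g] - 1L)
      out[fnames[i]] <- list(tfDecode(part, p$fields[[i]], ctx,
                                      c(path, fnames[i]), off + st - 1L))
    }
    out
  }
}

# ---------------------------------------------------------------------------
# encode

tfEncode <- function(value, def, ctx, path = character(0L)) {
  def <- resolveDef(def, ctx$table)
  p <- def@params
  r <- def@rules
  if (!is.null(r$empty) && dvEqual(value, r$empty$value)) return("")

  core <- switch(def@kind,
    constant = {
      if (!dvEqual(value, p$value))
        encodeError(sprintf("value does not equal the constant's value (%s)",
                            dvKey(p$value)), path)
      p$text
    },
    values = {
      dec <- r$decoded
      candidates <- Filter(function(t) {
        v <- if (!is.null(dec) && t %in% names(dec)) dec[[t]] else t
        dvEqual(v, value)
      }, p$texts)
      if (!length(candidates))
        encodeError(sprintf("value %s is not representable by this value set",
                            dvKey(value)), path)
      canonicalText(candidates, value, r)
    },
    regex = encodeRegexKind(value, p$pattern, r, path),
    regexes = {
      ok <- FALSE
      res <- NULL
      for (pat in p$patterns) {
        res <- tryCatch(encodeRegexKind(value, pat, r, path),
                        flatformatsEncodeError = function(e) NULL)
        if (!is.null(res)) { ok <- TRUE; break }
      }
      if (!ok)
        encodeError(sprintf("value %s matches none of the patterns",
                            dvKey(value)), path)
      res
    },
    integer = {
      v <- asScalarNumber(value)
      if (is.null(v) || is.logical(value) || v != floor(v))
        encodeError("value must be an integer", path)
      if (v < p$min || v > p$max)
        encodeError(sprintf("value %s out of interval [%s, %s]",
                            formatInt(v), p$min, p$max), path)
      formatInt(v)
    },
    unsigned_integer = {
      v <- asScalarNumber(value)
      if (is.null(v) || is.logical(value) || v != floor(v) || v < 0)
        encodeError("value must be an unsigned integer", path)
      if (v < p$min || v > p$max)
        encodeError(sprintf("value %s out of interval [%s, %s]",
                            formatInt(v), p$min, p$max), path)
      txt <- formatBase(v, p$base)
      if (p$prefix)
        txt <- paste0(switch(as.character(p$base), "2" = "0b", "8" = "0o",
                             "16" = "0x", ""), txt)
      txt
    },
    float = {
      v <- asScalarNumber(value)
      if (is.null(v) || is.logical(value))
        encodeError("value must be a number", path)
      lo <- if (p$minExcluded) v > p$min else v >= p$min
      hi <- if (p$maxExcluded) v < p$max else v <= p$max
      if (!lo || !hi)
        encodeError(sprintf("value %s out of interval", formatFloat(v)), path)
      formatFloat(v)
    },
    list_of = {
      if (!dvIsSequence(value))
        encodeError("value must be a sequence", path)
      n <- length(value)
      if (!is.na(p$length) && n != p$length)
        encodeError(sprintf("expected exactly %d elements, got %d",
                            p$length, n), path)
      if (n < p$minLength)
        encodeError(sprintf("expected at least %d elements, got %d",
                            p$minLength, n), path)
      if (!is.na(p$maxLength) && n > p$maxLength)
        encodeError(sprintf("expected at most %d elements, got %d",
                            p$maxLength, n), path)
      paste(vapply(seq_len(n), function(i)
        tfEncode(value[[i]], p$element, ctx, c(path, sprintf("[%d]", i))),
        character(1L)), collapse = p$separator)
    },
    labeled_list = {
      if (!dvIsMapping(value))
        encodeError("value must be a mapping label -> value", path)
      unknown <- setdiff(names(value), names(p$labels))
      if (length(unknown))
        encodeError(sprintf("unknown label(s): %s",
                            paste(unknown, collapse = ", ")), path)
      missing <- setdiff(p$required, names(value))
      if (length(missing))
        encodeError(sprintf("missing required label(s): %s",
                            paste(missing, collapse = ", ")), path)
      if (length(value) == 0L)
        encodeError("labeled list must contain at least one element", path)
      paste(vapply(names(value), function(lab)
        paste0(lab, p$internalSeparator,
               tfEncode(value[[lab]], p$labels[[lab]], ctx, c(path, lab))),
        character(1L)), collapse = p$separator)
    },
    tagged_list = {
      if (!dvIsMapping(value))
        encodeError("value must be a mapping tagname -> value", path)
      if (length(value) == 0L)
        encodeError("tagged list must contain at least one element", path)
      items <- vapply(names(value), function(name) {
        if (!fullMatch(p$namePattern, name))
          encodeError(sprintf("invalid tag name '%s'", name), path)
        for (code in names(p$codes)) {
          enc <- tryCatch(tfEncode(value[[name]], p$codes[[code]], ctx,
                                   c(path, name)),
                          flatformatsEncodeError = function(e) NULL)
          if (!is.null(enc))
            return(paste0(name, p$internalSeparator, code,
                          p$internalSeparator, enc))
        }
        encodeError(sprintf(
          "no tag type code can represent the value of '%s'", name),
          c(path, name))
      }, character(1L))
      paste(items, collapse = p$separator)
    },
    composed_of = {
      if (!dvIsMapping(value))
        encodeError("value must be a mapping field -> value", path)
      fnames <- names(p$fields)
      unknown <- setdiff(names(value), fnames)
      if (length(unknown))
        encodeError(sprintf("unknown field(s): %s",
                            paste(unknown, collapse = ", ")), path)
      present <- fnames %in% names(value)
      req <- p$nRequired
      if (req > 0L && !all(present[seq_len(req)]))
        encodeError(sprintf("missing required field '%s'",
                            fnames[which(!present[seq_len(req)])[1L]]), path)
      last <- if (any(present)) max(which(present)) else 0L
      if (last > 0L && !all(present[seq_len(last)]))
        encodeError(sprintf(
          "field '%s' is absent but a later field is present",
          fnames[which(!present[seq_len(last)])[1L]]), path)
      if (last == 0L) "" else
        paste(vapply(seq_len(last), function(i)
          tfEncode(value[[fnames[i]]], p$fields[[i]], ctx,
                   c(path, fnames[i])), character(1L)),
          collapse = p$separator)
    },
    one_of = {
      for (i in seq_along(p$alternatives)) {
        enc <- tryCatch(tfEncode(value, p$alternatives[[i]], ctx,
                                 c(path, sprintf("<%d>", i))),
                        flatformatsEncodeError = function(e) NULL)
        if (!is.null(enc)) return(finishEncode(enc, r, path))
      }
      encodeError(sprintf("value %s is representable by none of the %d alternatives",
                          dvKey(value), length(p$alternatives)), path)
    })
  finishEncode(core, r, path)
}

finishEncode <- function(core, r, path) {
  if (!is.null(r$must_match) && !fullMatch(r$must_match, core))
    encodeError(sprintf("encoded text does not satisfy pattern '%s'",
                        r$must_match), path)
  paste0(r$prefix %||% "", core, r$suffix %||% "")
}

canonicalText <- function(candidates, value, rules) {
  can <- rules$canonical
  if (!is.null(can)) {
    k <- dvKey(value)
    if (k %in% names(can)) return(can[[k]])
  }
  candidates[[1L]]
}

encodeRegexKind <- function(value, pattern, rules, path) {
  dec <- rules$decoded
  if (!is.null(dec)) {
    hits <- Filter(function(t) dvEqual(dec[[t]], value), names(dec))
    if (length(hits)) return(canonicalText(hits, value, rules))
  }
  if (isString(value) && fullMatch(pattern, value) &&
      !(!is.null(dec) && value %in% names(dec) &&
        !dvEqual(dec[[value]], value)))
    return(value)
  encodeError(sprintf("value %s cannot be written with pattern '%s'",
                      dvKey(value), pattern), path)
}

# ---------------------------------------------------------------------------
# exported methods

#' @describeIn decode decode a string against a datatype of a compiled
#'   specification.
#' @export
setMethod("decode", signature("character", "CompiledSpecification",
                              "character"),
          function(x, spec, datatype, ...) {
            stopifnot(length(x) == 1L)
            def <- getDatatype(spec, datatype)
            tfDecode(x, def, makeCtx(spec))
          })

#' @describeIn decode decode against a self-contained definition.
#' @export
setMethod("decode", signature("character", "DatatypeDefinition", "missing"),
          function(x, spec, datatype, ...) {
            stopifnot(length(x) == 1L)
            tfDecode(x, spec, makeCtx(NULL))
          })

#' @describeIn encode encode a value as a datatype of a compiled
#'   specification.
#' @export
setMethod("encode", signature("ANY", "CompiledSpecification", "character"),
          function(x, spec, datatype, ...) {
            def <- getDatatype(spec, datatype)
            tfEncode(x, def, makeCtx(spec))
          })

#' @describeIn encode encode against a self-contained definition.
#' @export
setMethod("encode", signature("ANY", "DatatypeDefinition", "missing"),
          function(x, spec, datatype, ...) {
            tfEncode(x, spec, makeCtx(NULL))
          })

tfIsValidEncoded <- function(text, def, ctx, matcher = NULL) {
  if (is.null(matcher)) {
    res <- bodyFor(def, ctx$table, ctx$cache)
    matcher <- list(pattern = paste0("^(?:", res$body, ")$"),
                    needsCheck = res$needsCheck)
  }
  if (!grepl(matcher$pattern, text, perl = TRUE)) return(FALSE)
  if (!matcher$needsCheck) return(TRUE)
  !is.null(tryCatch(list(tfDecode(text, def, ctx)),
                    flatformatsDecodeError = function(e) NULL))
}

#' @describeIn isValidEncoded validate a string against a datatype of a
#'   compiled specification.
#' @export
setMethod("isValidEncoded", signature("character", "CompiledSpecification",
                                      "character"),
          function(x, spec, datatype, ...) {
            stopifnot(length(x) == 1L)
            def <- getDatatype(spec, datatype)
            tfIsValidEncoded(x, def, makeCtx(spec),
                             spec@matchers[[datatype]])
          })

#' @describeIn isValidEncoded validate against a self-contained definition.
#' @export
setMethod("isValidEncoded", signature("character", "DatatypeDefinition",
                                      "missing"),
          function(x, spec, datatype, ...) {
            stopifnot(length(x) == 1L)
            tfIsValidEncoded(x, spec, makeCtx(NULL))
          })

tfIsValidDecoded <- function(value, def, ctx) {
  !is.null(tryCatch(list(tfEncode(value, def, ctx)),
                    flatformatsEncodeError = function(e) NULL))
}

#' @describeIn isValidDecoded validate a value against a datatype of a
#'   compiled specification.
#' @export
setMethod("isValidDecoded", signature("ANY", "CompiledSpecification",
                                      "character"),
          function(x, spec, datatype, ...) {
            tfIsValidDecoded(x, getDatatype(spec, datatype), makeCtx(spec))
          })

#' @describeIn isValidDecoded validate against a self-contained definition.
#' @export
setMethod("isValidDecoded", signature("ANY", "DatatypeDefinition", "missing"),
          function(x, spec, datatype, ...) {
            tfIsValidDecoded(x, spec, makeCtx(NULL))
          })
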