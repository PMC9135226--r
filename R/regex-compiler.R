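# Translation of resolved datatype definitions into anchored regular
# expressions.  Every definition gets a "body" pattern (non-capturing) whose
# accepted language equals the set of valid text representations, except
# that numeric interval membership, labeled-list required/duplicate checks
# and list-count checks after non-exclusive-separator parsing are enforced
# post-match (the pattern then accepts a superset and `needsCheck` is TRUE).

GROUP_CAP_DEFAULT <- 500L

resolveDef <- function(x, table) {
  seen <- character(0L)
  while (isRef(x)) {
    if (x$ref %in% seen)
      tfError("flatformatsCycleError",
              sprintf("circular reference through '%s'", x$ref),
              cycle = c(seen, x$ref))
    seen <- c(seen, x$ref)
    if (!x$ref %in% names(table))
      tfError("flatformatsUnresolvedReference",
              sprintf("unresolved datatype reference '%s'", x$ref))
    x <- table[[x$ref]]
  }
  x
}

# body + needsCheck for a definition; memoized by datatype name in `cache`.
bodyFor <- function(def, table, cache) {
  if (isRef(def)) {
    key <- def$ref
    if (!is.null(cache[[key]])) return(cache[[key]])
    def <- resolveDef(def, table)
  } else {
    key <- def@name
    if (!is.na(key) && !is.null(cache[[key]])) return(cache[[key]])
  }
  res <- buildBody(def, table, cache)
  if (!is.na(key)) cache[[key]] <- res
  res
}

repCount <- function(m, M) {
  # regex repetition suffix for between m and M further occurrences
  if (is.na(M) || is.infinite(M)) {
    if (m == 0L) "*" else sprintf("{%d,}", m)
  } else if (m == M) {
    if (m == 1L) "" else sprintf("{%d}", m)
  } else sprintf("{%d,%d}", m, M)
}

buildBody <- function(def, table, cache) {
  p <- def@params
  r <- def@rules
  sub <- function(x) bodyFor(x, table, cache)
  res <- switch(def@kind,
    constant = list(body = escapeRegex(p$text), needsCheck = FALSE),
    values = list(body = paste0(vapply(p$texts, escapeRegex, character(1L)),
                                collapse = "|"),
                  needsCheck = FALSE),
    regex = list(body = paste0("(?:", p$pattern, ")"), needsCheck = FALSE),
    regexes = list(body = paste0("(?:", p$patterns, ")", collapse = "|"),
                   needsCheck = FALSE),
    integer = list(body = "[+-]?[0-9]+", needsCheck = TRUE),
    unsigned_integer = {
      digits <- switch(as.character(p$base),
                       "2" = "[01]", "8" = "[0-7]", "10" = "[0-9]",
                       "16" = "[0-9A-Fa-f]")
      pre <- switch(as.character(p$base),
                    "2" = "(?:0[bB])?", "8" = "(?:0[oO])?",
                    "16" = "(?:0[xX])?", "")
      list(body = paste0(pre, digits, "+"), needsCheck = TRUE)
    },
    float = list(
      body = "[+-]?(?:[0-9]+(?:\\.[0-9]*)?|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?",
      needsCheck = TRUE),
    list_of = {
      e <- sub(p$element)
      E <- paste0("(?:", e$body, ")")
      S <- escapeRegex(p$separator)
      m <- p$minLength; M <- p$maxLength
      body <- if (!is.na(p$length) && p$length == 0L) "" else {
        core <- paste0(E, "(?:", S, E, ")",
                       repCount(max(m - 1L, 0L),
                                if (is.na(M)) NA else M - 1L))
        if (m == 0L) paste0("(?:", core, ")?") else core
      }
      list(body = body, needsCheck = e$needsCheck || !p$splitted)
    },
    labeled_list = {
      items <- vapply(names(p$labels), function(lab) {
        v <- sub(p$labels[[lab]])
        paste0(escapeRegex(lab), escapeRegex(p$internalSeparator),
               "(?:", v$body, ")")
      }, character(1L))
      item <- paste0("(?:", paste0(items, collapse = "|"), ")")
      S <- escapeRegex(p$separator)
      list(body = paste0(item, "(?:", S, item, ")*"), needsCheck = TRUE)
    },
    tagged_list = {
      I <- escapeRegex(p$internalSeparator)
      codeAlts <- vapply(names(p$codes), function(code) {
        v <- sub(p$codes[[code]])
        paste0(escapeRegex(code), I, "(?:", v$body, ")")
      }, character(1L))
      item <- paste0("(?:", p$namePattern, ")", I,
                     "(?:", paste0(codeAlts, collapse = "|"), ")")
      S <- escapeRegex(p$separator)
      list(body = paste0("(?:", item, ")(?:", S, "(?:", item, "))*"),
           needsCheck = TRUE)
    },
    composed_of = {
      bodies <- lapply(p$fields, sub)
      B <- vapply(bodies, function(b) paste0("(?:", b$body, ")"),
                  character(1L))
      S <- escapeRegex(p$separator)
      n <- length(B); req <- p$nRequired
      tail <- ""
      if (n > req) {
        for (i in seq(n, req + 1L)) {
          sep_i <- if (i > 1L) S else ""
          tail <- paste0("(?:", sep_i, B[i], tail, ")?")
        }
      }
      head <- if (req > 0L) paste0(B[1:req], collapse = S) else ""
      body <- paste0(head, tail)
      if (req == 0L && n > 0L) {
        # first optional field carries no separator; rebuild chain
        tail <- ""
        if (n > 1L) for (i in seq(n, 2L))
          tail <- paste0("(?:", S, B[i], tail, ")?")
        body <- paste0("(?:", B[1L], tail, ")?")
      }
      list(body = body,
           needsCheck = any(vapply(bodies, `[[`, logical(1L), "needsCheck")))
    },
    one_of = {
      alts <- lapply(p$alternatives, sub)
      list(body = paste0("(?:",
                         vapply(alts, `[[`, character(1L), "body"),
                         ")", collapse = "|"),
           needsCheck = any(vapply(alts, `[[`, logical(1L), "needsCheck")))
    })
  body <- res$body
  needsCheck <- res$needsCheck
  if (!is.null(r$prefix)) body <- paste0(escapeRegex(r$prefix), body)
  if (!is.null(r$suffix)) body <- paste0(body, escapeRegex(r$suffix))
  if (!is.null(r$must_match)) needsCheck <- TRUE
  if (!is.null(r$empty)) body <- paste0("(?:", body, ")?")
  list(body = body, needsCheck = needsCheck)
}

countCaptureGroups <- function(pattern) {
  # capturing "(" = not escaped, not followed by "?" (named groups "(?<" are
  # counted by engines as capturing, but we only emit them deliberately)
  m <- gregexpr("\\((\\?)?", pattern, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(0L)
  lens <- attr(m, "match.length")
  starts <- as.integer(m)
  esc <- vapply(starts, function(s) {
    nb <- 0L; i <- s - 1L
    while (i >= 1L && substr(pattern, i, i) == "\\") { nb <- nb + 1L; i <- i - 1L }
    nb %% 2L == 1L
  }, logical(1L))
  sum(lens == 1L & !esc)
}

#' Compile a datatype definition into a matcher
#'
#' Produces the anchored regular expression (and parsing strategy) for a
#' resolved definition.  Literal prefixes, suffixes and separators are
#' regex-escaped; `one_of` alternatives appear in listed order, so when two
#' alternatives both match, the parse is attributed to the earlier one.
#'
#' @param def a [DatatypeDefinition-class] (or a datatype name if `spec`
#'   is given).
#' @param spec optional [CompiledSpecification-class] providing the table
#'   that references in `def` resolve against.
#' @param groupCap maximum number of capturing groups permitted in the
#'   compiled pattern (guards against engine limits).
#' @return an object of class `CompiledMatcher`: a list with elements
#'   `pattern` (anchored regex source), `body` (unanchored), `strategy`
#'   (`"split"`, `"regex"` or `"hybrid"`) and `needsCheck` (whether
#'   post-match numeric/structural checks are required beyond the pattern).
#' @examples
#' d <- normalizeDefinition(list(constant = "ACGT"), "motif")
#' compileMatcher(d)$pattern
#' @export
compileMatcher <- function(def, spec = NULL, groupCap = GROUP_CAP_DEFAULT) {
  table <- if (!is.null(spec)) spec@table else list()
  if (isString(def)) def <- getDatatype(spec, def)
  cache <- new.env(parent = emptyenv())
  res <- bodyFor(def, table, cache)
  pattern <- paste0("^(?:", res$body, ")$")
  ng <- countCaptureGroups(pattern)
  if (ng > groupCap)
    tfError("flatformatsPatternTooComplex",
            sprintf("pattern for '%s' uses %d capturing groups (cap %d)",
                    def@name, ng, groupCap))
  tryCatch(suppressWarnings(grepl(pattern, "", perl = TRUE)),
           error = function(e)
             tfError("flatformatsSyntaxError",
                     sprintf("invalid regular expression compiled for '%s': %s",
                             def@name, conditionMessage(e))))
  compound <- def@kind %in% c("list_of", "labeled_list", "tagged_list",
                              "composed_of")
  strategy <- if (compound && isTRUE(def@params$splitted)) "split"
  else if (compound) "regex"
  else if (def@kind == "one_of") "hybrid"
  else "regex"
  structure(list(pattern = pattern, body = res$body,
                 strategy = strategy, needsCheck = res$needsCheck),
            class = "CompiledMatcher")
}

#' @export
print.CompiledMatcher <- function(x, ...) {
  cat(sprintf("CompiledMatcher (strategy: %s%s)\n  %s\n", x$strategy,
              if (x$needsCheck) ", with post-match checks" else "",
              x$pattern))
  invisible(x)
}

#' Derive the validation regex for a datatype
#'
#' Returns an anchored pattern usable for fast validation of the text
#' representation without building the decoded value.  For numeric-interval
#' datatypes the pattern describes the lexical envelope; interval membership
#' is enforced by [isValidEncoded()] as a post-match check.
#'
#' @inheritParams compileMatcher
#' @return a regex source string (anchored).
#' @export
deriveValueRegex <- function(def, spec = NULL) {
  compileMatcher(def, spec)$pattern
}

# Named-group pattern for extracting the top-level fields of a composed_of
# definition parsed with a non-exclusive separator.  Groups are g1..gn in
# field order (generated names cannot collide with user group names).
composedGroupPattern <- function(def, table, cache) {
  p <- def@params
  B <- vapply(seq_along(p$fields), function(i) {
    b <- bodyFor(p$fields[[i]], table, cache)
    paste0("(?<g", i, ">", b$body, ")")
  }, character(1L))
  S <- escapeRegex(p$separator)
  n <- length(B); req <- p$nRequired
  if (req == 0L) {
    tail <- ""
    if (n > 1L) for (i in seq(n, 2L))
      tail <- paste0("(?:", S, B[i], tail, ")?")
    return(paste0("^(?:", B[1L], tail, ")?$"))
  }
  tail <- ""
  if (n > req) for (i in seq(n, req + 1L))
    tail <- paste0("(?:", S, B[i], tail, ")?")
  paste0("^", paste0(B[1:req], collapse = S), tail, "$")
}
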