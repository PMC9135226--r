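# Internal helpers shared across the package.

KINDS <- c("constant", "values", "regex", "regexes",
           "integer", "unsigned_integer", "float",
           "list_of", "labeled_list", "tagged_list", "composed_of", "one_of")

SCOPES <- c("line", "unit", "section", "file")

DIALECT_VERSION <- "1.0"

IDENTIFIER_RE <- "^[A-Za-z_][A-Za-z0-9_]*(::[A-Za-z_][A-Za-z0-9_]*)*$"

#' @noRd
isString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' @noRd
isCount <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

#' @noRd
isFlag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# A reference to a named datatype, used wherever an inline definition would
# otherwise appear.
tfRef <- function(name) structure(list(ref = name), class = "tfRef")

isRef <- function(x) inherits(x, "tfRef")

#' @noRd
escapeRegex <- function(x) {
  gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", x, perl = TRUE)
}

# strsplit() drops trailing empty strings; formats with empty trailing fields
# (e.g. "tpg|BK003456|") need them kept.
splitKeep <- function(text, sep) {
  if (!nzchar(sep)) return(strsplit(text, "", fixed = TRUE)[[1L]])
  if (!nzchar(text)) return("")
  hits <- gregexpr(sep, text, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(text)
  starts <- c(1L, hits + nchar(sep))
  ends <- c(hits - 1L, nchar(text))
  substring(text, starts, ends)
}

# Positions (1-based) at which each part returned by splitKeep starts.
splitKeepStarts <- function(text, sep) {
  if (!nzchar(sep) || !nzchar(text)) return(1L)
  hits <- gregexpr(sep, text, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(1L)
  c(1L, as.integer(hits) + nchar(sep))
}

#' @noRd
fullMatch <- function(pattern, text) {
  grepl(paste0("^(?:", pattern, ")$"), text, perl = TRUE)
}

# --- DataValue helpers -------------------------------------------------------
# A decoded value is one of: NULL, logical(1), numeric(1)/integer(1),
# character(1), an unnamed list (sequence) or a named list (mapping).

dvIsMapping <- function(x) is.list(x) && (length(x) == 0L || !is.null(names(x)))

dvIsSequence <- function(x) is.list(x) && (length(x) == 0L || is.null(names(x)))

# Structural equality with integer/double unification (3L equals 3.0).
dvEqual <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  if (is.list(a) || is.list(b)) {
    if (!is.list(a) || !is.list(b)) return(FALSE)
    if (length(a) != length(b)) return(FALSE)
    na <- names(a); nb <- names(b)
    if (is.null(na) != is.null(nb)) {
      # a named empty list and an unnamed empty list are both empty
      if (length(a) == 0L) return(TRUE)
      return(FALSE)
    }
    if (!is.null(na)) {
      if (anyDuplicated(na) || anyDuplicated(nb)) return(FALSE)
      if (!setequal(na, nb)) return(FALSE)
      return(all(vapply(na, function(k) dvEqual(a[[k]], b[[k]]), logical(1L))))
    }
    return(all(vapply(seq_along(a), function(i) dvEqual(a[[i]], b[[i]]),
                      logical(1L))))
  }
  if (is.numeric(a) && is.numeric(b)) {
    return(length(a) == 1L && length(b) == 1L && !is.na(a) && !is.na(b) &&
             as.numeric(a) == as.numeric(b))
  }
  identical(unname(a), unname(b))
}

# Stable string key for a value (used for canonical-text lookup in
# non-injective transformation maps).
dvKey <- function(x) {
  if (is.null(x)) return("null")
  if (is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) &&
      abs(x) < 2^53) {
    return(format(x, scientific = FALSE, trim = TRUE))
  }
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                                digits = NA))
}

# Shortest decimal representation of a double that reads back equal.
formatFloat <- function(x) {
  for (d in c(1L, 6L, 15L, 17L)) {
    s <- format(x, digits = d, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) == x) return(s)
  }
  format(x, digits = 17L, trim = TRUE)
}

formatInt <- function(x) format(x, scientific = FALSE, trim = TRUE)

# Convert a non-negative integer to base 2/8/10/16 (uppercase digits).
formatBase <- function(x, base) {
  if (base == 10L) return(formatInt(x))
  digits <- "0123456789ABCDEF"
  if (x == 0) return("0")
  out <- character(0L)
  while (x > 0) {
    out <- c(substr(digits, (x %% base) + 1L, (x %% base) + 1L), out)
    x <- x %/% base
  }
  paste(out, collapse = "")
}

parseBase <- function(text, base) {
  v <- suppressWarnings(strtoi(text, base = base))
  if (is.na(v)) {
    # beyond .Machine$integer.max: accumulate in double precision
    digits <- strsplit(toupper(text), "")[[1L]]
    vals <- match(digits, strsplit("0123456789ABCDEF", "")[[1L]]) - 1L
    v <- 0
    for (d in vals) v <- v * base + d
  }
  v
}

asScalarNumber <- function(x) {
  if (is.numeric(x) && length(x) == 1L && !is.na(x)) as.numeric(x) else NULL
}

# Run code with a private, seeded RNG stream, restoring global RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# --- condition constructors --------------------------------------------------

tfError <- function(class, message, ...) {
  stop(structure(class = c(class, "flatformatsError", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

decodeError <- function(message, path = character(0L), offset = NA_integer_,
                        line = NA_integer_) {
  stop(structure(
    class = c("flatformatsDecodeError", "flatformatsError", "error",
              "condition"),
    list(message = message, call = NULL, path = path, offset = offset,
         line = line)))
}

encodeError <- function(message, path = character(0L)) {
  stop(structure(
    class = c("flatformatsEncodeError", "flatformatsError", "error",
              "condition"),
    list(message = message, call = NULL, path = path)))
}
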