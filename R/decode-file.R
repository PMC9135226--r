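# File decoding with line / unit / section / file scopes, and
# element-at-a-time streaming that still validates the whole-file structure.

structuralError <- function(message, line = NA_integer_) {
  stop(structure(
    class = c("flatformatsStructuralError", "flatformatsDecodeError",
              "flatformatsError", "error", "condition"),
    list(message = message, call = NULL, line = line,
         path = character(0L), offset = NA_integer_)))
}

newRecord <- function(value, span, datatype) {
  structure(list(value = value, span = span, datatype = datatype),
            class = "DecodedRecord")
}

#' @export
print.DecodedRecord <- function(x, ...) {
  cat(sprintf("DecodedRecord [%d-%d] (%s): %s\n", x$span[1L], x$span[2L],
              x$datatype,
              jsonlite::toJSON(x$value, auto_unbox = TRUE, null = "null",
                               digits = NA)))
  invisible(x)
}

readTextLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sub("\r$", "", lines)  # universal newlines
}

lineDecodeError <- function(e, lineno) {
  stop(structure(
    class = class(e),
    list(message = sprintf("line %d: %s", lineno, conditionMessage(e)),
         call = NULL, path = e$path, offset = e$offset, line = lineno)))
}

#' Decode a file of text-format records
#'
#' Applies a datatype definition to a file, with the definition scope
#' controlling which part of the file one record spans: one line (`line`),
#' a fixed number of lines (`unit`), a maximal run of matching lines
#' (`section`), or the entire file (`file`).  File scope requires a
#' `composed_of` definition whose fields are `list_of` definitions over
#' line datatypes (the sections); ordering of sections and presence of
#' required sections are enforced.  With `streaming = TRUE` under file
#' scope, one record per line is emitted (labelled with its section's field
#' name) instead of a single whole-file record, while the structural
#' constraints are still checked across the stream.
#'
#' @param path path to the input file.
#' @param spec a [CompiledSpecification-class].
#' @param datatype name of the datatype to apply.
#' @param scope one of `"line"`, `"unit"`, `"section"`, `"file"`; defaults
#'   to the scope declared by the datatype, or `"line"`.
#' @param unitSize lines per record for unit scope (defaults to the
#'   datatype's declared `unit_size`).
#' @param streaming emit innermost elements one at a time (file scope).
#' @param callback optional function called with each record as it is
#'   produced (the decoded records are returned regardless).
#' @return a list of `DecodedRecord` objects (fields `value`, `span`,
#'   `datatype`).
#' @seealso [decode()]
#' @export
decodeFile <- function(path, spec, datatype, scope = NULL, unitSize = NULL,
                       streaming = FALSE, callback = NULL) {
  def <- getDatatype(spec, datatype)
  ctx <- makeCtx(spec)
  scope <- scope %||% (if (nzchar(def@scope)) def@scope else "line")
  if (!scope %in% SCOPES)
    tfError("flatformatsUsageError",
            sprintf("invalid scope '%s'", scope))
  lines <- readTextLines(path)
  records <- list()
  emit <- function(rec) {
    records[[length(records) + 1L]] <<- rec
    if (!is.null(callback)) callback(rec)
    invisible(NULL)
  }
  if (scope == "line") {
    for (i in seq_along(lines)) {
      v <- withCallingHandlers(
        tfDecode(lines[[i]], def, ctx),
        flatformatsDecodeError = function(e) lineDecodeError(e, i))
      emit(newRecord(v, c(i, i), datatype))
    }
  } else if (scope == "unit") {
    usize <- as.integer(unitSize %||% def@unitSize)
    if (is.na(usize) || usize < 1L)
      tfError("flatformatsUsageError",
              "unit scope requires a positive unit size")
    if (length(lines) %% usize != 0L)
      structuralError(sprintf(
        "file has %d lines, not a multiple of the unit size %d",
        length(lines), usize), length(lines))
    starts <- seq(1L, length.out = length(lines) %/% usize, by = usize)
    for (s in starts) {
      chunk <- paste(lines[s:(s + usize - 1L)], collapse = "\n")
      v <- withCallingHandlers(
        tfDecode(chunk, def, ctx),
        flatformatsDecodeError = function(e) lineDecodeError(e, s))
      emit(newRecord(v, c(s, s + usize - 1L), datatype))
    }
  } else if (scope == "section") {
    sdef <- resolveDef(def, ctx$table)
    if (sdef@kind != "list_of")
      tfError("flatformatsUsageError",
              "section scope requires a list_of definition over a line datatype")
    i <- 1L
    while (i <= length(lines)) {
      run <- sectionRun(lines, i, sdef, ctx)
      if (run$n == 0L)
        structuralError(sprintf(
          "line %d does not start a valid '%s' section", i, datatype), i)
      vals <- lapply(seq_len(run$n), function(k)
        tfDecode(lines[[i + k - 1L]], sdef@params$element, ctx))
      checkListCount(run$n, sdef@params, "", character(0L), 1L)
      emit(newRecord(vals, c(i, i + run$n - 1L), datatype))
      i <- i + run$n
    }
  } else { # file scope
    fdef <- resolveDef(def, ctx$table)
    if (fdef@kind != "composed_of")
      tfError("flatformatsUsageError",
              "file scope requires a composed_of definition whose fields are sections (list_of over line datatypes)")
    p <- fdef@params
    fnames <- names(p$fields)
    i <- 1L
    fileValue <- list()
    for (fi in seq_along(p$fields)) {
      sdef <- resolveDef(p$fields[[fi]], ctx$table)
      if (sdef@kind != "list_of")
        tfError("flatformatsUsageError", sprintf(
          "file-scope section '%s' must be a list_of definition",
          fnames[fi]))
      run <- sectionRun(lines, i, sdef, ctx)
      minL <- if (!is.na(sdef@params$length)) sdef@params$length
      else sdef@params$minLength
      required <- fi <= p$nRequired
      if (required && run$n < minL)
        structuralError(sprintf(
          "section '%s' requires at least %d line(s) but %d found at line %d (content before or instead of a required section?)",
          fnames[fi], minL, run$n, i), i)
      if (!required && run$n < minL && run$n > 0L)
        structuralError(sprintf(
          "section '%s' has %d line(s), fewer than its minimum %d",
          fnames[fi], run$n, minL), i)
      vals <- list()
      for (k in seq_len(run$n)) {
        v <- withCallingHandlers(
          tfDecode(lines[[i + k - 1L]], sdef@params$element, ctx),
          flatformatsDecodeError = function(e)
            lineDecodeError(e, i + k - 1L))
        if (streaming) emit(newRecord(v, c(i + k - 1L, i + k - 1L),
                                      fnames[fi]))
        else vals[[k]] <- v
      }
      if (!streaming) fileValue[[fnames[fi]]] <- vals
      i <- i + run$n
    }
    if (i <= length(lines))
      structuralError(sprintf(
        "line %d does not belong to any section (all sections already closed)",
        i), i)
    if (!streaming)
      emit(newRecord(fileValue, c(1L, max(length(lines), 1L)), datatype))
  }
  records
}

# maximal run of consecutive lines matching the element of a list_of
# section, bounded by the section's maximum length (maximal munch)
sectionRun <- function(lines, start, sdef, ctx) {
  maxL <- if (!is.na(sdef@params$length)) sdef@params$length
  else sdef@params$maxLength
  n <- 0L
  i <- start
  while (i <= length(lines) &&
         (is.na(maxL) || n < maxL) &&
         tfIsValidEncoded(lines[[i]], sdef@params$element, ctx)) {
    n <- n + 1L
    i <- i + 1L
  }
  list(n = n)
}
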