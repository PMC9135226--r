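#' DatatypeDefinition: one named datatype of a format specification
#'
#' A datatype definition describes one piece of a text format: a scalar
#' (constant, value set, regular expression, numeric interval) or a compound
#' (list, labeled list, tagged list, ordered composition, set of
#' alternatives).  Definitions are normally built by [normalizeDefinition()]
#' or obtained from a [CompiledSpecification-class] via [getDatatype()].
#'
#' @slot name name of the datatype (possibly namespace-qualified,
#'   e.g. `"gfa::tag"`).
#' @slot kind one of the twelve definition kinds: `constant`, `values`,
#'   `regex`, `regexes`, `integer`, `unsigned_integer`, `float`, `list_of`,
#'   `labeled_list`, `tagged_list`, `composed_of`, `one_of`.
#' @slot params kind-specific parameters (intervals, element definitions,
#'   separators, ...), normalized with defaults filled in.
#' @slot rules optional validation/formatting/transformation rules: constant
#'   `prefix`/`suffix`, a `decoded` map (text to value), an `empty` rule
#'   (value represented by the empty string), a `canonical` choice of text
#'   form, and an extra `must_match` pattern.
#' @slot scope for file decoding: `""` (none), `"line"`, `"unit"`,
#'   `"section"` or `"file"`.
#' @slot unitSize number of lines per unit (only for unit scope).
#' @seealso [normalizeDefinition()], [decode()], [encode()]
#' @export
setClass("DatatypeDefinition",
         representation(name = "character",
                        kind = "character",
                        params = "list",
                        rules = "list",
                        scope = "character",
                        unitSize = "integer"),
         prototype(name = NA_character_, kind = "constant",
                   params = list(), rules = list(),
                   scope = "", unitSize = NA_integer_))

setValidity("DatatypeDefinition", function(object) {
  msgs <- character(0L)
  if (length(object@kind) != 1L || !(object@kind %in% KINDS))
    msgs <- c(msgs, sprintf("kind must be one of: %s",
                            paste(KINDS, collapse = ", ")))
  if (length(object@scope) != 1L ||
      !(object@scope %in% c("", SCOPES)))
    msgs <- c(msgs, "scope must be '' or one of line, unit, section, file")
  if (identical(object@scope, "unit") && is.na(object@unitSize))
    msgs <- c(msgs, "unit scope requires unitSize")
  if (!is.na(object@unitSize) && object@unitSize < 1L)
    msgs <- c(msgs, "unitSize must be a positive integer")
  if (length(msgs)) msgs else TRUE
})

#' CompiledSpecification: a resolved, compiled format specification
#'
#' The result of [loadSpecification()]: a table mapping datatype names to
#' fully resolved [DatatypeDefinition-class] objects, after include
#' resolution, reference resolution, circular-dependency checking and
#' compilation of per-datatype matchers (anchored regular expressions, plus
#' split-based plans where an exclusive delimiter allows them).
#'
#' @slot table named list of [DatatypeDefinition-class] objects.
#' @slot matchers named list of compiled matchers, parallel to `table`.
#' @slot testdata named list of embedded test data trees (possibly empty).
#' @slot provenance source path(s) the specification was loaded from.
#' @slot dialectVersion version string of the specification dialect.
#' @slot cache internal memo of compiled sub-patterns (not serialized).
#' @seealso [loadSpecification()], [datatypeNames()], [getDatatype()]
#' @export
setClass("CompiledSpecification",
         representation(table = "list",
                        matchers = "list",
                        testdata = "list",
                        provenance = "character",
                        dialectVersion = "character",
                        cache = "environment"),
         prototype(table = list(), matchers = list(), testdata = list(),
                   provenance = character(0L),
                   dialectVersion = DIALECT_VERSION))

setValidity("CompiledSpecification", function(object) {
  msgs <- character(0L)
  nm <- names(object@table)
  if (length(object@table) && (is.null(nm) || any(!nzchar(nm))))
    msgs <- c(msgs, "all datatypes must be named")
  if (anyDuplicated(nm))
    msgs <- c(msgs, "datatype names must be unique")
  if (!identical(sort(names(object@matchers)), sort(nm %||% character(0L))))
    msgs <- c(msgs, "matchers must parallel the datatype table")
  if (length(msgs)) msgs else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' TestReport: result of running embedded test data
#'
#' Produced by [runTestdata()].  Aggregates, per datatype, the number of
#' passed and failed expectations; failures carry the case, the direction
#' (decode/encode/validate) and the observed versus expected outcome.
#'
#' @slot passed total number of passed expectations.
#' @slot failed total number of failed expectations.
#' @slot failures data.frame with columns `datatype`, `direction`, `case`,
#'   `detail`.
#' @export
setClass("TestReport",
         representation(passed = "integer", failed = "integer",
                        failures = "data.frame"),
         prototype(passed = 0L, failed = 0L,
                   failures = data.frame(datatype = character(0L),
                                         direction = character(0L),
                                         case = character(0L),
                                         detail = character(0L),
                                         stringsAsFactors = FALSE)))

setMethod("show", "DatatypeDefinition", function(object) {
  cat(sprintf("DatatypeDefinition '%s' (kind: %s)\n",
              object@name, object@kind))
  if (nzchar(object@scope))
    cat(sprintf("  scope: %s%s\n", object@scope,
                if (!is.na(object@unitSize))
                  sprintf(" (unit size %d)", object@unitSize) else ""))
  if (length(object@rules))
    cat("  rules:", paste(names(object@rules), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "CompiledSpecification", function(object) {
  cat(sprintf("CompiledSpecification (%d datatypes, dialect %s)\n",
              length(object@table), object@dialectVersion))
  if (length(object@provenance))
    cat("  source:", paste(object@provenance, collapse = ", "), "\n")
  nm <- sort(names(object@table))
  if (length(nm) > 12L) nm <- c(nm[1:12], sprintf("... (%d more)",
                                                  length(object@table) - 12L))
  cat("  datatypes:", paste(nm, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "TestReport", function(object) {
  cat(sprintf("TestReport: %d passed, %d failed\n",
              object@passed, object@failed))
  if (object@failed > 0L) {
    df <- object@failures
    for (i in seq_len(min(nrow(df), 10L))) {
      cat(sprintf("  [%s] %s: %s -- %s\n", df$datatype[i], df$direction[i],
                  df$case[i], df$detail[i]))
    }
    if (nrow(df) > 10L) cat(sprintf("  ... and %d more\n", nrow(df) - 10L))
  }
  invisible(NULL)
})
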