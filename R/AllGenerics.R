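#' Names of the datatypes in a specification
#'
#' @param x a [CompiledSpecification-class].
#' @return character vector of datatype names, sorted.
#' @export
setGeneric("datatypeNames", function(x) standardGeneric("datatypeNames"))

#' @rdname datatypeNames
#' @export
setMethod("datatypeNames", "CompiledSpecification", function(x) {
  sort(names(x@table))
})

#' Retrieve one datatype definition from a specification
#'
#' @param x a [CompiledSpecification-class].
#' @param name datatype name.
#' @return the [DatatypeDefinition-class] registered under `name`.
#' @export
setGeneric("getDatatype", function(x, name) standardGeneric("getDatatype"))

#' @rdname getDatatype
#' @export
setMethod("getDatatype", "CompiledSpecification", function(x, name) {
  stopifnot(isString(name))
  if (!name %in% names(x@table))
    tfError("flatformatsUnknownDatatype",
            sprintf("unknown datatype '%s'; available: %s", name,
                    paste(sort(names(x@table)), collapse = ", ")))
  x@table[[name]]
})

#' Kind of a datatype definition
#'
#' @param x a [DatatypeDefinition-class].
#' @return one of the twelve kind tags.
#' @export
setGeneric("datatypeKind", function(x) standardGeneric("datatypeKind"))

#' @rdname datatypeKind
#' @export
setMethod("datatypeKind", "DatatypeDefinition", function(x) x@kind)

#' Decode a text representation into the value it represents
#'
#' Matches `x` against the datatype definition and applies its
#' transformation rules (decoded-value maps, empty-text rule).  Compound
#' kinds return sequences (`list_of`) or string-keyed mappings
#' (`composed_of`, `labeled_list`, `tagged_list`); `one_of` returns the
#' first matching alternative's value.
#'
#' @param x a single string (the encoded form).
#' @param spec a [CompiledSpecification-class].
#' @param datatype name of the datatype to decode as.
#' @param ... unused.
#' @return the decoded value: `NULL`, a logical, numeric or character
#'   scalar, an unnamed list (sequence) or a named list (mapping).
#' @seealso [encode()], [isValidEncoded()], [decodeFile()]
#' @export
setGeneric("decode", function(x, spec, datatype, ...) standardGeneric("decode"))

#' Encode a value into its text representation
#'
#' Inverse of [decode()]: writes the text representation of `x` under the
#' datatype definition.  When several representations exist, the canonical
#' (first-listed) text form is emitted.
#'
#' @param x the value to encode.
#' @param spec a [CompiledSpecification-class].
#' @param datatype name of the datatype to encode as.
#' @param ... unused.
#' @return a single string.
#' @export
setGeneric("encode", function(x, spec, datatype, ...) standardGeneric("encode"))

#' Validate a text representation against a datatype
#'
#' `isValidEncoded(x)` is `TRUE` exactly when [decode()] would succeed on
#' `x`.  Where the datatype carries no post-match numeric or structural
#' constraints the check is a single anchored regular-expression match.
#'
#' @inheritParams decode
#' @return `TRUE` or `FALSE`.
#' @export
setGeneric("isValidEncoded",
           function(x, spec, datatype, ...) standardGeneric("isValidEncoded"))

#' Validate a decoded value against a datatype
#'
#' `isValidDecoded(x)` is `TRUE` exactly when [encode()] would succeed on
#' `x`, i.e. when the value is representable in the format.
#'
#' @inheritParams encode
#' @return `TRUE` or `FALSE`.
#' @export
setGeneric("isValidDecoded",
           function(x, spec, datatype, ...) standardGeneric("isValidDecoded"))
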