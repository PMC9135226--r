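# The specification-language data model: structural validation of datatype
# definition trees, normalization into DatatypeDefinition objects, and the
# inverse serialization.
#
# Dialect summary.  A definition tree is one of:
#   * a scalar string  -> constant (at top level) / datatype reference (in a
#     sub-definition position); the sigil "@name" is a reference anywhere;
#   * an unnamed list of scalars -> shorthand for a `values` definition;
#   * a mapping with exactly one kind key (constant, values, regex, regexes,
#     integer, unsigned_integer, float, list_of, labeled_list, tagged_list,
#     composed_of, one_of) holding the kind payload, plus optional sibling
#     rule keys (prefix, suffix, decoded, empty, canonical, must_match,
#     splitted_by, separator, internal_separator, length, min_length,
#     max_length, required, tagname, n_required, scope, unit_size).

RULE_KEYS_COMMON <- c("prefix", "suffix", "empty", "must_match",
                      "scope", "unit_size")
RULE_KEYS <- list(
  constant         = c("decoded"),
  values           = c("decoded", "canonical"),
  regex            = c("decoded", "canonical"),
  regexes          = c("decoded", "canonical"),
  integer          = character(0L),
  unsigned_integer = character(0L),
  float            = character(0L),
  list_of          = c("length", "min_length", "max_length",
                       "splitted_by", "separator"),
  labeled_list     = c("required", "internal_separator",
                       "splitted_by", "separator"),
  tagged_list      = c("tagname", "internal_separator",
                       "splitted_by", "separator"),
  composed_of      = c("n_required", "splitted_by", "separator"),
  one_of           = character(0L)
)

validKeysFor <- function(kind) {
  sort(unique(c(KINDS, RULE_KEYS_COMMON, RULE_KEYS[[kind]])))
}

diag_row <- function(path, message, valid_keys = character(0L)) {
  data.frame(path = paste(path, collapse = "/"),
             message = message,
             valid_keys = paste(valid_keys, collapse = ", "),
             stringsAsFactors = FALSE)
}

emptyDiagnostics <- function() {
  data.frame(path = character(0L), message = character(0L),
             valid_keys = character(0L), stringsAsFactors = FALSE)
}

isScalar <- function(x) {
  !is.list(x) && is.atomic(x) && length(x) == 1L && !is.na(x)
}

regexCompiles <- function(pattern) {
  isString(pattern) &&
    !inherits(tryCatch(
      suppressWarnings(grepl(paste0("(?:", pattern, ")"), "", perl = TRUE)),
      error = function(e) e), "error")
}

# composed_of payload: either an ordered mapping or a list of single-entry
# mappings; returns a named list of field trees, or NULL if malformed.
composedFields <- function(payload) {
  if (is.list(payload) && is.null(names(payload))) {
    fields <- list()
    for (el in payload) {
      if (!is.list(el) || length(el) != 1L || is.null(names(el))) return(NULL)
      fields[names(el)] <- el
    }
    return(fields)
  }
  if (is.list(payload) && !is.null(names(payload)) && length(payload) >= 1L)
    return(payload)
  NULL
}

#' Structurally validate a datatype definition tree
#'
#' Checks whether a parsed document node is a syntactically valid datatype
#' definition in the specification dialect.  Problems are reported as
#' diagnostics, each carrying a path into the tree, a message, and the set
#' of keys valid at that context; an empty result means the tree is valid.
#'
#' @param tree a parsed document node (named list / string / list), as
#'   obtained from a YAML or JSON reader.
#' @param path internal; path prefix used in diagnostics.
#' @param topLevel internal; whether `tree` sits at datatype top level
#'   (where a bare string is a constant) or in a sub-definition position
#'   (where a bare string is a reference).
#' @return a data.frame with columns `path`, `message`, `valid_keys`;
#'   zero rows iff the tree is valid.
#' @examples
#' validateDefinitionTree(list(constant = "1.0"))          # valid
#' validateDefinitionTree(list(integer = list(min = 5, max = 1)))
#' @export
validateDefinitionTree <- function(tree, path = character(0L),
                                   topLevel = TRUE) {
  d <- emptyDiagnostics()
  # shorthand forms
  if (is.character(tree) && length(tree) == 1L && !is.na(tree)) {
    txt <- tree
    if (startsWith(txt, "@")) {
      ref <- substring(txt, 2L)
      if (!grepl(IDENTIFIER_RE, ref))
        d <- rbind(d, diag_row(path, sprintf(
          "invalid reference name '%s'", ref)))
      return(d)
    }
    if (!topLevel && !grepl(IDENTIFIER_RE, txt))
      d <- rbind(d, diag_row(path, sprintf(
        "invalid datatype reference '%s' (in a sub-definition position a bare string names another datatype)",
        txt)))
    return(d)
  }
  if (isScalar(tree)) {
    if (topLevel) return(d)  # scalar constant shorthand
    return(rbind(d, diag_row(path,
      "a scalar in a sub-definition position must be a datatype name string")))
  }
  if (is.list(tree) && is.null(names(tree))) {
    # values shorthand
    if (length(tree) == 0L)
      return(rbind(d, diag_row(path, "empty list is not a valid definition")))
    bad <- !vapply(tree, isScalar, logical(1L))
    if (any(bad))
      d <- rbind(d, diag_row(path,
        "values shorthand list must contain only scalar values"))
    return(d)
  }
  if (!is.list(tree) || is.null(names(tree)))
    return(rbind(d, diag_row(path,
      "definition must be a mapping, a string, or a list of values",
      KINDS)))

  keys <- names(tree)
  kindKeys <- intersect(keys, KINDS)
  if (length(kindKeys) == 0L)
    return(rbind(d, diag_row(path,
      "no kind key: exactly one of the definition kinds is required", KINDS)))
  if (length(kindKeys) > 1L)
    return(rbind(d, diag_row(path, sprintf(
      "multiple kind keys (%s): a definition has exactly one kind",
      paste(kindKeys, collapse = ", ")), KINDS)))
  kind <- kindKeys
  valid <- validKeysFor(kind)
  unknown <- setdiff(keys, valid)
  if (length(unknown))
    d <- rbind(d, diag_row(path, sprintf("unknown key(s): %s",
                                         paste(unknown, collapse = ", ")),
                           valid))
  payload <- tree[[kind]]
  ppath <- c(path, kind)

  subcheck <- function(node, subpath) {
    validateDefinitionTree(node, subpath, topLevel = FALSE)
  }

  d <- rbind(d, switch(kind,
    constant = {
      if (!isScalar(payload) || is.logical(payload))
        diag_row(ppath, "constant payload must be a string or a number")
      else emptyDiagnostics()
    },
    values = {
      dd <- emptyDiagnostics()
      if (!is.list(payload) || !is.null(names(payload)) ||
          length(payload) < 1L ||
          !all(vapply(payload, isScalar, logical(1L))))
        dd <- rbind(dd, diag_row(ppath,
          "values payload must be a non-empty list of scalar values"))
      else if (anyDuplicated(vapply(payload, as.character, character(1L))))
        dd <- rbind(dd, diag_row(ppath, "duplicated member in values"))
      dd
    },
    regex = {
      if (!regexCompiles(payload))
        diag_row(ppath, "regex payload must be a valid regular expression")
      else emptyDiagnostics()
    },
    regexes = {
      dd <- emptyDiagnostics()
      if (!is.list(payload) || !is.null(names(payload)) ||
          length(payload) < 1L)
        dd <- rbind(dd, diag_row(ppath,
          "regexes payload must be a non-empty list of patterns"))
      else for (i in seq_along(payload))
        if (!regexCompiles(payload[[i]]))
          dd <- rbind(dd, diag_row(c(ppath, as.character(i)),
            "invalid regular expression"))
      dd
    },
    integer = checkInterval(payload, ppath, integerOnly = TRUE,
                            unsigned = FALSE),
    unsigned_integer = checkInterval(payload, ppath, integerOnly = TRUE,
                                     unsigned = TRUE),
    float = checkInterval(payload, ppath, integerOnly = FALSE,
                          unsigned = FALSE),
    list_of = {
      dd <- subcheck(payload, ppath)
      dd <- rbind(dd, checkLengths(tree, path))
      dd
    },
    labeled_list = {
      dd <- emptyDiagnostics()
      if (!is.list(payload) || is.null(names(payload)) ||
          length(payload) < 1L)
        dd <- rbind(dd, diag_row(ppath,
          "labeled_list payload must be a mapping label -> definition"))
      else {
        for (lab in names(payload))
          dd <- rbind(dd, subcheck(payload[[lab]], c(ppath, lab)))
        req <- tree[["required"]]
        if (!is.null(req)) {
          reqv <- tryCatch(vapply(req, as.character, character(1L)),
                           error = function(e) NULL)
          if (is.null(reqv) || !all(reqv %in% names(payload)))
            dd <- rbind(dd, diag_row(c(path, "required"),
              "required must list a subset of the labels"))
        }
      }
      dd
    },
    tagged_list = {
      dd <- emptyDiagnostics()
      if (!is.list(payload) || is.null(names(payload)) ||
          length(payload) < 1L)
        dd <- rbind(dd, diag_row(ppath,
          "tagged_list payload must be a mapping type-code -> definition"))
      else for (code in names(payload))
        dd <- rbind(dd, subcheck(payload[[code]], c(ppath, code)))
      tn <- tree[["tagname"]]
      if (!is.null(tn) && !regexCompiles(tn))
        dd <- rbind(dd, diag_row(c(path, "tagname"),
          "tagname must be a valid regular expression"))
      dd
    },
    composed_of = {
      dd <- emptyDiagnostics()
      fields <- composedFields(payload)
      if (is.null(fields))
        dd <- rbind(dd, diag_row(ppath,
          "composed_of payload must be an ordered mapping field -> definition (or a list of single-entry mappings)"))
      else {
        if (anyDuplicated(names(fields)))
          dd <- rbind(dd, diag_row(ppath, "duplicated field name"))
        for (f in names(fields))
          dd <- rbind(dd, subcheck(fields[[f]], c(ppath, f)))
        nr <- tree[["n_required"]]
        if (!is.null(nr) && (!isCount(nr) || nr > length(fields)))
          dd <- rbind(dd, diag_row(c(path, "n_required"),
            "n_required must be an integer between 0 and the number of fields"))
      }
      dd
    },
    one_of = {
      dd <- emptyDiagnostics()
      if (!is.list(payload) || !is.null(names(payload)) ||
          length(payload) < 2L)
        dd <- rbind(dd, diag_row(ppath,
          "one_of payload must be an unnamed list of at least 2 alternatives"))
      else for (i in seq_along(payload))
        dd <- rbind(dd, subcheck(payload[[i]], c(ppath, as.character(i))))
      dd
    }))

  d <- rbind(d, checkRules(tree, path, kind))
  d
}

checkInterval <- function(payload, ppath, integerOnly, unsigned) {
  dd <- emptyDiagnostics()
  if (is.null(payload)) payload <- list()
  if (!is.list(payload) || (length(payload) && is.null(names(payload))))
    return(diag_row(ppath, "interval payload must be a mapping",
                    c("min", "max",
                      if (unsigned) c("base", "prefix"),
                      if (!integerOnly) c("min_excluded", "max_excluded"))))
  valid <- c("min", "max",
             if (unsigned) c("base", "prefix"),
             if (!integerOnly) c("min_excluded", "max_excluded"))
  unknown <- setdiff(names(payload), valid)
  if (length(unknown))
    dd <- rbind(dd, diag_row(ppath, sprintf("unknown interval key(s): %s",
                                            paste(unknown, collapse = ", ")),
                             valid))
  chknum <- function(key) {
    v <- payload[[key]]
    if (is.null(v)) return(NULL)
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      return(diag_row(c(ppath, key), "bound must be a number"))
    if (integerOnly && v != floor(v))
      return(diag_row(c(ppath, key), "bound must be an integer"))
    if (unsigned && v < 0)
      return(diag_row(c(ppath, key), "bound must be non-negative"))
    NULL
  }
  for (k in c("min", "max")) {
    r <- chknum(k)
    if (!is.null(r)) dd <- rbind(dd, r)
  }
  mn <- asScalarNumber(payload[["min"]])
  mx <- asScalarNumber(payload[["max"]])
  if (!is.null(mn) && !is.null(mx)) {
    if (mn > mx)
      dd <- rbind(dd, diag_row(ppath, "empty interval (min > max)"))
    else if (!integerOnly && mn == mx &&
             (isTRUE(payload[["min_excluded"]]) ||
              isTRUE(payload[["max_excluded"]])))
      dd <- rbind(dd, diag_row(ppath,
        "empty interval (single point with an open bound)"))
  }
  if (unsigned) {
    b <- payload[["base"]]
    if (!is.null(b) && !(is.numeric(b) && length(b) == 1L &&
                         b %in% c(2, 8, 10, 16)))
      dd <- rbind(dd, diag_row(c(ppath, "base"),
        "base must be one of 2, 8, 10, 16"))
    p <- payload[["prefix"]]
    if (!is.null(p) && !isFlag(p))
      dd <- rbind(dd, diag_row(c(ppath, "prefix"),
        "prefix must be a boolean"))
  }
  if (!integerOnly) {
    for (k in c("min_excluded", "max_excluded")) {
      v <- payload[[k]]
      if (!is.null(v) && !isFlag(v))
        dd <- rbind(dd, diag_row(c(ppath, k), "must be a boolean"))
    }
  }
  dd
}

checkLengths <- function(tree, path) {
  dd <- emptyDiagnostics()
  for (k in c("length", "min_length", "max_length")) {
    v <- tree[[k]]
    if (!is.null(v) && !isCount(v))
      dd <- rbind(dd, diag_row(c(path, k),
        "length constraint must be a non-negative integer"))
  }
  if (!is.null(tree[["length"]]) &&
      (!is.null(tree[["min_length"]]) || !is.null(tree[["max_length"]])))
    dd <- rbind(dd, diag_row(path,
      "exact length excludes min_length/max_length"))
  mn <- asScalarNumber(tree[["min_length"]])
  mx <- asScalarNumber(tree[["max_length"]])
  if (!is.null(mn) && !is.null(mx) && mn > mx)
    dd <- rbind(dd, diag_row(path, "min_length > max_length"))
  dd
}

checkRules <- function(tree, path, kind) {
  dd <- emptyDiagnostics()
  for (k in c("prefix", "suffix")) {
    v <- tree[[k]]
    if (!is.null(v) && !isString(v))
      dd <- rbind(dd, diag_row(c(path, k), "must be a literal string"))
  }
  for (k in c("splitted_by", "internal_separator")) {
    v <- tree[[k]]
    if (!is.null(v) && !(isString(v) && nzchar(v)))
      dd <- rbind(dd, diag_row(c(path, k), "must be a non-empty string"))
  }
  v <- tree[["separator"]]
  if (!is.null(v) && !isString(v))
    dd <- rbind(dd, diag_row(c(path, "separator"), "must be a string"))
  if (!is.null(tree[["splitted_by"]]) && !is.null(tree[["separator"]]))
    dd <- rbind(dd, diag_row(path,
      "splitted_by (exclusive delimiter) and separator are mutually exclusive"))
  v <- tree[["decoded"]]
  if (!is.null(v) && (!is.list(v) || is.null(names(v)) ||
                      anyDuplicated(names(v))))
    dd <- rbind(dd, diag_row(c(path, "decoded"),
      "decoded must be a mapping with distinct text keys"))
  v <- tree[["must_match"]]
  if (!is.null(v) && !regexCompiles(v))
    dd <- rbind(dd, diag_row(c(path, "must_match"),
      "must_match must be a valid regular expression"))
  v <- tree[["canonical"]]
  if (!is.null(v) && !(isString(v) ||
                       (is.list(v) && !is.null(names(v)))))
    dd <- rbind(dd, diag_row(c(path, "canonical"),
      "canonical must be a string or a mapping value -> text"))
  sc <- tree[["scope"]]
  if (!is.null(sc) && !(isString(sc) && sc %in% SCOPES))
    dd <- rbind(dd, diag_row(c(path, "scope"), sprintf(
      "scope must be one of: %s", paste(SCOPES, collapse = ", "))))
  us <- tree[["unit_size"]]
  if (!is.null(us) && (!isCount(us) || us < 1))
    dd <- rbind(dd, diag_row(c(path, "unit_size"),
      "unit_size must be a positive integer"))
  if (identical(sc, "unit") && is.null(us))
    dd <- rbind(dd, diag_row(path, "unit scope requires unit_size"))
  if (!is.null(us) && !identical(sc, "unit"))
    dd <- rbind(dd, diag_row(path, "unit_size requires scope: unit"))
  dd
}

scalarText <- function(x) {
  if (is.character(x)) return(x)
  if (is.numeric(x)) {
    if (x == floor(x)) return(formatInt(x))
    return(formatFloat(x))
  }
  as.character(x)
}

#' Normalize a definition tree into a DatatypeDefinition
#'
#' Expands shorthand forms (a bare string meaning a constant, a plain list
#' meaning a value set), fills in defaults (tab as the list/field delimiter,
#' `:` as the internal separator, closed float bounds, base 10, all fields
#' required), and returns the canonical in-memory form of the definition.
#'
#' @param tree a definition tree for which [validateDefinitionTree()]
#'   reports no diagnostics.
#' @param name name to give the datatype.
#' @return a [DatatypeDefinition-class].
#' @examples
#' normalizeDefinition("ACGT", "motif")           # constant shorthand
#' normalizeDefinition(list("T", "F"), "strand")  # values shorthand
#' @export
normalizeDefinition <- function(tree, name = "anonymous") {
  d <- validateDefinitionTree(tree)
  if (nrow(d))
    tfError("flatformatsSyntaxError",
            sprintf("invalid definition '%s': %s%s", name, d$message[1L],
                    if (nzchar(d$path[1L]))
                      sprintf(" (at %s)", d$path[1L]) else ""),
            diagnostics = d)
  normalizeNode(tree, name, topLevel = TRUE)
}

# Normalize a node in a sub-definition position: bare strings are
# references, everything else is an inline definition.
normalizeSub <- function(node, name) {
  if (is.character(node) && length(node) == 1L) {
    if (startsWith(node, "@")) return(tfRef(substring(node, 2L)))
    return(tfRef(node))
  }
  normalizeNode(node, name, topLevel = FALSE)
}

normalizeNode <- function(tree, name, topLevel) {
  if (is.character(tree) && length(tree) == 1L && startsWith(tree, "@")) {
    tfError("flatformatsSyntaxError", sprintf(
      "datatype '%s': a reference cannot be a top-level definition", name))
  }
  if (isScalar(tree)) {
    tree <- list(constant = tree)
  } else if (is.list(tree) && is.null(names(tree)) &&
             all(vapply(tree, isScalar, logical(1L)))) {
    tree <- list(values = tree)
  }
  kind <- intersect(names(tree), KINDS)
  payload <- tree[[kind]]
  rules <- list()
  for (k in c("prefix", "suffix", "must_match"))
    if (!is.null(tree[[k]])) rules[[k]] <- tree[[k]]
  if (!is.null(tree[["decoded"]])) {
    dec <- tree[["decoded"]]
    rules[["decoded"]] <- dec
  }
  if ("empty" %in% names(tree)) rules[["empty"]] <- list(value = tree[["empty"]])
  if (!is.null(tree[["canonical"]])) {
    can <- tree[["canonical"]]
    if (isString(can)) can <- structure(list(can), names = can)
    rules[["canonical"]] <- can
  }
  scope <- tree[["scope"]] %||% ""
  unitSize <- if (!is.null(tree[["unit_size"]]))
    as.integer(tree[["unit_size"]]) else NA_integer_

  sepDefaults <- function(defaultSep = "\t") {
    if (!is.null(tree[["splitted_by"]]))
      list(separator = tree[["splitted_by"]], splitted = TRUE)
    else if (!is.null(tree[["separator"]]))
      list(separator = tree[["separator"]], splitted = FALSE)
    else list(separator = defaultSep, splitted = TRUE)
  }

  params <- switch(kind,
    constant = {
      txt <- scalarText(payload)
      val <- txt
      dec <- rules[["decoded"]]
      if (!is.null(dec) && txt %in% names(dec)) val <- dec[[txt]]
      list(text = txt, value = val)
    },
    values = {
      list(texts = vapply(payload, scalarText, character(1L)))
    },
    regex = list(pattern = payload),
    regexes = list(patterns = vapply(payload, as.character, character(1L))),
    integer = {
      p <- payload %||% list()
      list(min = asScalarNumber(p[["min"]]) %||% -Inf,
           max = asScalarNumber(p[["max"]]) %||% Inf)
    },
    unsigned_integer = {
      p <- payload %||% list()
      list(min = asScalarNumber(p[["min"]]) %||% 0,
           max = asScalarNumber(p[["max"]]) %||% Inf,
           base = as.integer(p[["base"]] %||% 10L),
           prefix = isTRUE(p[["prefix"]]))
    },
    float = {
      p <- payload %||% list()
      list(min = asScalarNumber(p[["min"]]) %||% -Inf,
           max = asScalarNumber(p[["max"]]) %||% Inf,
           minExcluded = isTRUE(p[["min_excluded"]]),
           maxExcluded = isTRUE(p[["max_excluded"]]))
    },
    list_of = {
      sp <- sepDefaults()
      len <- tree[["length"]]
      list(element = normalizeSub(payload, paste0(name, ".element")),
           length = if (is.null(len)) NA_integer_ else as.integer(len),
           minLength = if (!is.null(len)) as.integer(len) else
             as.integer(tree[["min_length"]] %||% 1L),
           maxLength = if (!is.null(len)) as.integer(len) else
             if (is.null(tree[["max_length"]])) NA_integer_ else
               as.integer(tree[["max_length"]]),
           separator = sp$separator, splitted = sp$splitted)
    },
    labeled_list = {
      sp <- sepDefaults()
      labs <- lapply(names(payload), function(lab)
        normalizeSub(payload[[lab]], paste0(name, ".", lab)))
      names(labs) <- names(payload)
      list(labels = labs,
           required = vapply(tree[["required"]] %||% list(),
                             as.character, character(1L)),
           internalSeparator = tree[["internal_separator"]] %||% ":",
           separator = sp$separator, splitted = sp$splitted)
    },
    tagged_list = {
      sp <- sepDefaults()
      codes <- lapply(names(payload), function(code)
        normalizeSub(payload[[code]], paste0(name, ".", code)))
      names(codes) <- names(payload)
      list(namePattern = tree[["tagname"]] %||% "[A-Za-z][A-Za-z0-9]*",
           codes = codes,
           internalSeparator = tree[["internal_separator"]] %||% ":",
           separator = sp$separator, splitted = sp$splitted)
    },
    composed_of = {
      sp <- sepDefaults()
      fieldTrees <- composedFields(payload)
      fields <- lapply(names(fieldTrees), function(f)
        normalizeSub(fieldTrees[[f]], paste0(name, ".", f)))
      names(fields) <- names(fieldTrees)
      list(fields = fields,
           nRequired = as.integer(tree[["n_required"]] %||% length(fields)),
           separator = sp$separator, splitted = sp$splitted)
    },
    one_of = {
      alts <- lapply(seq_along(payload), function(i)
        normalizeSub(payload[[i]], paste0(name, ".alt", i)))
      list(alternatives = alts)
    })

  methods::new("DatatypeDefinition", name = name, kind = kind,
               params = params, rules = rules, scope = scope,
               unitSize = unitSize)
}

#' Serialize a DatatypeDefinition back to a definition tree
#'
#' Inverse of [normalizeDefinition()]: produces an explicit (shorthand-free)
#' tree which normalizes back to an equivalent definition.  Used for the
#' pre-compiled specification archive.
#'
#' @param def a [DatatypeDefinition-class].
#' @return a named list (definition tree).
#' @export
serializeDefinition <- function(def) {
  stopifnot(methods::is(def, "DatatypeDefinition"))
  serSub <- function(x) {
    if (isRef(x)) return(paste0("@", x$ref))
    serializeDefinition(x)
  }
  p <- def@params
  tree <- switch(def@kind,
    constant = list(constant = p$text),
    values = list(values = as.list(p$texts)),
    regex = list(regex = p$pattern),
    regexes = list(regexes = as.list(p$patterns)),
    integer = list(integer = c(
      if (is.finite(p$min)) list(min = p$min),
      if (is.finite(p$max)) list(max = p$max))),
    unsigned_integer = list(unsigned_integer = c(
      list(min = p$min),
      if (is.finite(p$max)) list(max = p$max),
      list(base = p$base, prefix = p$prefix))),
    float = list(float = c(
      if (is.finite(p$min)) list(min = p$min),
      if (is.finite(p$max)) list(max = p$max),
      list(min_excluded = p$minExcluded, max_excluded = p$maxExcluded))),
    list_of = c(list(list_of = serSub(p$element)),
      if (!is.na(p$length)) list(length = p$length)
      else c(list(min_length = p$minLength),
             if (!is.na(p$maxLength)) list(max_length = p$maxLength))),
    labeled_list = c(list(labeled_list = lapply(p$labels, serSub)),
      if (length(p$required)) list(required = as.list(p$required)),
      list(internal_separator = p$internalSeparator)),
    tagged_list = list(tagged_list = lapply(p$codes, serSub),
                       tagname = p$namePattern,
                       internal_separator = p$internalSeparator),
    composed_of = list(
      composed_of = lapply(names(p$fields), function(f)
        structure(list(serSub(p$fields[[f]])), names = f)),
      n_required = p$nRequired),
    one_of = list(one_of = lapply(p$alternatives, serSub)))

  if (def@kind %in% c("list_of", "labeled_list", "tagged_list",
                      "composed_of")) {
    tree[[if (p$splitted) "splitted_by" else "separator"]] <- p$separator
  }
  r <- def@rules
  for (k in c("prefix", "suffix", "must_match"))
    if (!is.null(r[[k]])) tree[[k]] <- r[[k]]
  if (!is.null(r$decoded)) tree$decoded <- r$decoded
  if (!is.null(r$empty)) tree["empty"] <- list(r$empty$value)
  if (!is.null(r$canonical)) tree$canonical <- r$canonical
  if (nzchar(def@scope)) tree$scope <- def@scope
  if (!is.na(def@unitSize)) tree$unit_size <- def@unitSize
  tree
}
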