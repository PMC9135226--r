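# Loading of specification documents: YAML/JSON parsing, section checking,
# recursive include resolution (with namespaces, whitelists and overrides),
# reference resolution over a dependency DAG with depth-first cycle
# detection, matcher compilation, and the pre-compiled archive.

SECTION_KEYS <- c("datatypes", "testdata", "include", "namespace")

looksLikeJson <- function(text) {
  grepl("^\\s*[{\\[]", text)
}

parseDocument <- function(pathOrText) {
  isPath <- !grepl("\n", pathOrText, fixed = TRUE) &&
    file.exists(pathOrText)
  text <- if (isPath)
    paste(readLines(pathOrText, warn = FALSE), collapse = "\n")
  else pathOrText
  useJson <- if (isPath && grepl("\\.json$", pathOrText,
                                 ignore.case = TRUE)) TRUE
  else if (isPath && grepl("\\.ya?ml$", pathOrText, ignore.case = TRUE)) FALSE
  else looksLikeJson(text)
  doc <- tryCatch(
    if (useJson) jsonlite::fromJSON(text, simplifyVector = FALSE)
    else yaml::yaml.load(text, handlers = list(
      seq = function(x) x,
      # YAML 1.2 core-schema booleans: only true/false, so that names
      # such as "n" or "y" remain strings
      "bool#yes" = function(x) if (tolower(x) == "true") TRUE else x,
      "bool#no" = function(x) if (tolower(x) == "false") FALSE else x)),
    error = function(e)
      tfError("flatformatsDocumentError",
              sprintf("cannot parse %s document%s: %s",
                      if (useJson) "JSON" else "YAML",
                      if (isPath) paste0(" '", pathOrText, "'") else "",
                      conditionMessage(e))))
  list(doc = doc, path = if (isPath) pathOrText else NA_character_)
}

parseSpecSource <- function(pathOrText) {
  pd <- parseDocument(pathOrText)
  doc <- pd$doc
  if (!is.list(doc) || is.null(names(doc)))
    tfError("flatformatsSyntaxError",
            "a specification document must be a mapping of sections")
  extra <- setdiff(names(doc), SECTION_KEYS)
  if (length(extra))
    tfError("flatformatsSyntaxError",
            sprintf("unknown section(s): %s (valid sections: %s)",
                    paste(extra, collapse = ", "),
                    paste(SECTION_KEYS, collapse = ", ")))
  dts <- doc[["datatypes"]] %||% list()
  if (!is.list(dts) || (length(dts) && is.null(names(dts))))
    tfError("flatformatsSyntaxError",
            "the datatypes section must be a mapping name -> definition")
  bad <- names(dts)[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", names(dts))]
  if (length(bad))
    tfError("flatformatsSyntaxError",
            sprintf("invalid datatype name(s): %s",
                    paste(bad, collapse = ", ")))
  ns <- doc[["namespace"]]
  if (!is.null(ns) && !isString(ns))
    tfError("flatformatsSyntaxError", "namespace must be a string")
  list(datatypes = dts,
       testdata = doc[["testdata"]] %||% list(),
       include = doc[["include"]] %||% list(),
       namespace = ns,
       path = pd$path,
       dir = if (is.na(pd$path)) "." else dirname(pd$path))
}

# Rewrite datatype references inside a definition tree according to a
# rename map (used when namespacing included specifications).
rewriteTreeRefs <- function(tree, rename, topLevel = TRUE) {
  rewriteName <- function(s) {
    core <- if (startsWith(s, "@")) substring(s, 2L) else s
    sig <- if (startsWith(s, "@")) "@" else ""
    if (core %in% names(rename)) paste0(sig, rename[[core]]) else s
  }
  if (is.character(tree) && length(tree) == 1L) {
    if (topLevel && !startsWith(tree, "@")) return(tree)  # constant shorthand
    return(rewriteName(tree))
  }
  if (!is.list(tree) || is.null(names(tree))) return(tree)
  kind <- intersect(names(tree), KINDS)
  if (length(kind) != 1L) return(tree)
  sub <- function(x) rewriteTreeRefs(x, rename, topLevel = FALSE)
  if (kind == "list_of") {
    tree[[kind]] <- sub(tree[[kind]])
  } else if (kind %in% c("labeled_list", "tagged_list")) {
    tree[[kind]] <- lapply(tree[[kind]], sub)
  } else if (kind == "composed_of") {
    payload <- tree[[kind]]
    if (is.list(payload) && is.null(names(payload))) {
      tree[[kind]] <- lapply(payload, function(el) {
        el[[1L]] <- sub(el[[1L]]); el
      })
    } else if (is.list(payload)) {
      tree[[kind]] <- lapply(payload, sub)
    }
  } else if (kind == "one_of") {
    tree[[kind]] <- lapply(tree[[kind]], sub)
  }
  tree
}

# Names of datatypes referenced (directly) by a definition tree.
treeRefs <- function(tree, topLevel = TRUE) {
  if (is.character(tree) && length(tree) == 1L) {
    if (startsWith(tree, "@")) return(substring(tree, 2L))
    if (topLevel) return(character(0L))
    return(tree)
  }
  if (!is.list(tree) || is.null(names(tree))) return(character(0L))
  kind <- intersect(names(tree), KINDS)
  if (length(kind) != 1L) return(character(0L))
  payload <- tree[[kind]]
  subs <- switch(kind,
    list_of = list(payload),
    labeled_list = ,
    tagged_list = unname(payload),
    composed_of = {
      f <- composedFields(payload)
      if (is.null(f)) list() else unname(f)
    },
    one_of = payload,
    list())
  unique(unlist(lapply(subs, treeRefs, topLevel = FALSE)))
}

deepMergeTree <- function(base, override) {
  if (is.list(override) && !is.null(names(override)) &&
      is.list(base) && !is.null(names(base))) {
    for (k in names(override)) {
      if (k %in% names(base)) {
        merged <- deepMergeTree(base[[k]], override[[k]])
        base[k] <- list(merged)
      } else {
        base[k] <- override[k]
      }
    }
    return(base)
  }
  override
}

#' Resolve the include section of a specification source
#'
#' Recursively loads included specification files, applies their namespace
#' prefixes to the imported datatype names (rewriting internal references),
#' restricts imports to an optional whitelist (plus the transitive
#' dependencies needed to keep references resolvable) and applies override
#' trees that replace sub-components of imported definitions.
#'
#' An include entry is either a path string or a mapping with keys `path`,
#' optional `datatypes` (whitelist) and optional `override`
#' (name -> partial definition tree).
#'
#' @param source a parsed specification source, as an internal structure or
#'   a path/text accepted by the loader.
#' @param loadedStack paths already being loaded (include-cycle detection).
#' @return the merged source (sections `datatypes` and `testdata`).
#' @export
resolveIncludes <- function(source, loadedStack = character(0L)) {
  if (is.character(source)) source <- parseSpecSource(source)
  acc_dt <- list()
  acc_td <- list()
  addDatatype <- function(name, tree) {
    if (name %in% names(acc_dt)) {
      if (!identical(acc_dt[[name]], tree))
        tfError("flatformatsNameCollision",
                sprintf("datatype '%s' defined more than once with different definitions; use a namespace or an explicit override",
                        name))
      return(invisible(NULL))
    }
    acc_dt[[name]] <<- tree
  }
  for (entry in source$include) {
    if (isString(entry)) entry <- list(path = entry)
    if (!is.list(entry) || !isString(entry[["path"]]))
      tfError("flatformatsSyntaxError",
              "each include entry must be a path or a mapping with a 'path' key")
    ipath <- entry[["path"]]
    if (!file.exists(ipath) && !is.null(source$dir))
      ipath <- file.path(source$dir, entry[["path"]])
    if (!file.exists(ipath))
      tfError("flatformatsMissingInclude",
              sprintf("include file not found: '%s'", entry[["path"]]))
    ipath <- normalizePath(ipath)
    if (ipath %in% loadedStack)
      tfError("flatformatsIncludeCycle",
              sprintf("include cycle detected: %s",
                      paste(c(loadedStack, ipath), collapse = " -> ")),
              cycle = c(loadedStack, ipath))
    isrc <- parseSpecSource(ipath)
    imerged <- resolveIncludes(isrc, c(loadedStack, ipath))
    idt <- imerged$datatypes
    itd <- imerged$testdata
    ns <- isrc$namespace
    if (!is.null(ns)) {
      rename <- structure(as.list(paste0(ns, "::", names(idt))),
                          names = names(idt))
      idt <- structure(lapply(idt, rewriteTreeRefs, rename = rename),
                       names = unlist(rename))
      if (length(itd)) names(itd) <- vapply(names(itd), function(n)
        rename[[n]] %||% n, character(1L))
    }
    wl <- entry[["datatypes"]]
    if (!is.null(wl)) {
      wl <- vapply(wl, as.character, character(1L))
      if (!is.null(ns))
        wl <- ifelse(wl %in% names(idt), wl, paste0(ns, "::", wl))
      missing <- setdiff(wl, names(idt))
      if (length(missing))
        tfError("flatformatsUnresolvedReference",
                sprintf("whitelisted datatype(s) not found in '%s': %s",
                        entry[["path"]], paste(missing, collapse = ", ")))
      keep <- character(0L)
      todo <- wl
      while (length(todo)) {
        n <- todo[[1L]]; todo <- todo[-1L]
        if (n %in% keep) next
        keep <- c(keep, n)
        todo <- c(todo, intersect(treeRefs(idt[[n]]), names(idt)))
      }
      idt <- idt[intersect(names(idt), keep)]
      itd <- itd[intersect(names(itd), keep)]
    }
    ov <- entry[["override"]]
    if (!is.null(ov)) {
      if (!is.list(ov) || is.null(names(ov)))
        tfError("flatformatsSyntaxError",
                "override must be a mapping datatype -> partial definition")
      for (name in names(ov)) {
        key <- if (name %in% names(idt)) name
        else if (!is.null(ns) && paste0(ns, "::", name) %in% names(idt))
          paste0(ns, "::", name)
        else tfError("flatformatsOverrideError",
                     sprintf("override path not found: no imported datatype '%s'",
                             name))
        idt[[key]] <- deepMergeTree(idt[[key]], ov[[name]])
      }
    }
    for (n in names(idt)) addDatatype(n, idt[[n]])
    for (n in names(itd)) if (!n %in% names(acc_td)) acc_td[[n]] <- itd[[n]]
  }
  for (n in names(source$datatypes)) addDatatype(n, source$datatypes[[n]])
  for (n in names(source$testdata)) acc_td[[n]] <- source$testdata[[n]]
  list(datatypes = acc_dt, testdata = acc_td,
       path = source$path, dir = source$dir)
}

# ---------------------------------------------------------------------------
# dependency graph and cycle check

refsOfDefinition <- function(def) {
  out <- character(0L)
  walk <- function(x) {
    if (isRef(x)) { out <<- c(out, x$ref); return(invisible(NULL)) }
    if (!methods::is(x, "DatatypeDefinition")) return(invisible(NULL))
    p <- x@params
    switch(x@kind,
      list_of = walk(p$element),
      labeled_list = for (l in p$labels) walk(l),
      tagged_list = for (c_ in p$codes) walk(c_),
      composed_of = for (f in p$fields) walk(f),
      one_of = for (a in p$alternatives) walk(a),
      NULL)
    invisible(NULL)
  }
  walk(def)
  unique(out)
}

#' Dependency graph of the datatypes of a specification
#'
#' Builds the directed graph with an edge A -> B whenever the definition of
#' datatype A references datatype B.
#'
#' @param x a [CompiledSpecification-class] or a named list of
#'   [DatatypeDefinition-class] objects.
#' @return a list with elements `nodes` (character) and `edges`
#'   (data.frame with columns `from`, `to`).
#' @export
dependencyGraph <- function(x) {
  table <- if (methods::is(x, "CompiledSpecification")) x@table else x
  edges <- do.call(rbind, c(list(
    data.frame(from = character(0L), to = character(0L),
               stringsAsFactors = FALSE)),
    lapply(names(table), function(n) {
      refs <- refsOfDefinition(table[[n]])
      if (!length(refs)) return(NULL)
      data.frame(from = n, to = refs, stringsAsFactors = FALSE)
    })))
  list(nodes = names(table) %||% character(0L), edges = edges)
}

#' Check a dependency graph for circular references
#'
#' Depth-first cycle detection.  Returns invisibly when the graph is
#' acyclic; otherwise signals a condition of class `flatformatsCycleError`
#' whose `cycle` field carries one witness cycle in dependency order
#' (first and last element equal).
#'
#' @param graph a graph as returned by [dependencyGraph()].
#' @return invisible `TRUE` when acyclic.
#' @examples
#' g <- list(nodes = c("a", "b"),
#'           edges = data.frame(from = "a", to = "b"))
#' checkAcyclic(g)
#' @export
checkAcyclic <- function(graph) {
  nodes <- graph$nodes
  adj <- split(graph$edges$to, factor(graph$edges$from, levels = nodes))
  color <- structure(rep("white", length(nodes)), names = nodes)
  stack <- character(0L)
  visit <- function(n) {
    color[[n]] <<- "grey"
    stack <<- c(stack, n)
    for (m in adj[[n]]) {
      if (!m %in% nodes) next
      if (color[[m]] == "grey") {
        cyc <- c(stack[seq(match(m, stack), length(stack))], m)
        tfError("flatformatsCycleError",
                sprintf("circular reference: %s",
                        paste(cyc, collapse = " -> ")),
                cycle = cyc)
      }
      if (color[[m]] == "white") visit(m)
    }
    color[[n]] <<- "black"
    stack <<- stack[-length(stack)]
    invisible(NULL)
  }
  for (n in nodes) if (color[[n]] == "white") visit(n)
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# full load

compileTable <- function(table, cache) {
  matchers <- list()
  for (n in names(table)) {
    def <- table[[n]]
    res <- bodyFor(tfRef(n), table, cache)
    pattern <- paste0("^(?:", res$body, ")$")
    ng <- countCaptureGroups(pattern)
    if (ng > GROUP_CAP_DEFAULT)
      tfError("flatformatsPatternTooComplex",
              sprintf("pattern for '%s' uses %d capturing groups (cap %d)",
                      n, ng, GROUP_CAP_DEFAULT))
    tryCatch(suppressWarnings(grepl(pattern, "", perl = TRUE)),
             error = function(e)
               tfError("flatformatsSyntaxError", sprintf(
                 "invalid regular expression compiled for '%s': %s",
                 n, conditionMessage(e))))
    compound <- def@kind %in% c("list_of", "labeled_list", "tagged_list",
                                "composed_of")
    matchers[[n]] <- list(
      pattern = pattern, body = res$body,
      strategy = if (compound && isTRUE(def@params$splitted)) "split"
      else if (compound) "regex"
      else if (def@kind == "one_of") "hybrid" else "regex",
      needsCheck = res$needsCheck)
  }
  matchers
}

buildSpecification <- function(datatypes, testdata = list(),
                               provenance = character(0L)) {
  diags <- emptyDiagnostics()
  for (n in names(datatypes)) {
    d <- validateDefinitionTree(datatypes[[n]])
    if (nrow(d)) {
      d$path <- paste0(n, ifelse(nzchar(d$path), "/", ""), d$path)
      diags <- rbind(diags, d)
    }
  }
  if (nrow(diags))
    tfError("flatformatsSyntaxError",
            paste0("specification syntax error(s):\n",
                   paste(sprintf("  at %s: %s%s", diags$path, diags$message,
                                 ifelse(nzchar(diags$valid_keys),
                                        sprintf(" [valid keys: %s]",
                                                diags$valid_keys), "")),
                         collapse = "\n")),
            diagnostics = diags)
  table <- lapply(names(datatypes), function(n)
    normalizeNode(datatypes[[n]], n, topLevel = TRUE))
  names(table) <- names(datatypes)
  # reference closure
  for (n in names(table)) {
    refs <- refsOfDefinition(table[[n]])
    missing <- setdiff(refs, names(table))
    if (length(missing))
      tfError("flatformatsUnresolvedReference",
              sprintf("datatype '%s' references undefined datatype(s): %s",
                      n, paste(missing, collapse = ", ")))
  }
  checkAcyclic(dependencyGraph(table))
  cache <- new.env(parent = emptyenv())
  matchers <- compileTable(table, cache)
  methods::new("CompiledSpecification", table = table, matchers = matchers,
               testdata = testdata, provenance = provenance,
               dialectVersion = DIALECT_VERSION, cache = cache)
}

#' Load (and compile) a format specification
#'
#' Parses a specification document (YAML or JSON, given as a file path or as
#' document text), resolves its include section recursively, checks the
#' dialect syntax, resolves datatype references (rejecting circular
#' references), and compiles a matcher for every datatype.  A pre-compiled
#' archive written by [saveCompiled()] is recognized and loaded directly.
#'
#' @param pathOrText path to a `.yaml`/`.yml`/`.json` specification file
#'   (or a pre-compiled archive), or the document text itself.
#' @return a [CompiledSpecification-class].
#' @examples
#' spec <- loadSpecification("datatypes: {x: {constant: 'A'}}")
#' datatypeNames(spec)
#' @export
loadSpecification <- function(pathOrText) {
  pd <- tryCatch(parseDocument(pathOrText),
                 flatformatsDocumentError = function(e) e)
  if (!inherits(pd, "error") && is.list(pd$doc) &&
      !is.null(pd$doc[["flatformats_compiled"]])) {
    return(loadCompiled(pathOrText))
  }
  if (inherits(pd, "error")) stop(pd)
  src <- parseSpecSource(pathOrText)
  stack <- if (!is.na(src$path)) normalizePath(src$path) else character(0L)
  merged <- resolveIncludes(src, stack)
  buildSpecification(merged$datatypes, merged$testdata,
                     provenance = if (!is.na(src$path)) src$path
                     else character(0L))
}

# ---------------------------------------------------------------------------
# pre-compiled archive

#' Save a compiled specification to a file
#'
#' Writes a versioned archive of the fully resolved datatype table (as a
#' JSON document); matchers are re-derived on load from the stored
#' definitions, which keeps the archive engine-independent.
#'
#' @param spec a [CompiledSpecification-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @seealso [loadCompiled()]
#' @export
saveCompiled <- function(spec, path) {
  stopifnot(methods::is(spec, "CompiledSpecification"))
  obj <- list(flatformats_compiled = spec@dialectVersion,
              provenance = as.list(spec@provenance),
              datatypes = lapply(spec@table, serializeDefinition),
              testdata = spec@testdata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Load a pre-compiled specification archive
#'
#' @param path archive written by [saveCompiled()] with the same dialect
#'   version.
#' @return a [CompiledSpecification-class] behaviourally identical to the
#'   one that was saved.
#' @export
loadCompiled <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                             collapse = "\n"), simplifyVector = FALSE),
    error = function(e)
      tfError("flatformatsCorruptArchive",
              sprintf("corrupt pre-compiled archive '%s': %s", path,
                      conditionMessage(e))))
  if (!is.list(doc) || is.null(doc[["flatformats_compiled"]]) ||
      !is.list(doc[["datatypes"]]))
    tfError("flatformatsCorruptArchive",
            sprintf("corrupt pre-compiled archive '%s': missing keys", path))
  ver <- doc[["flatformats_compiled"]]
  if (!identical(as.character(ver), DIALECT_VERSION))
    tfError("flatformatsVersionMismatch",
            sprintf("archive dialect version '%s' does not match '%s'",
                    ver, DIALECT_VERSION))
  buildSpecification(doc[["datatypes"]], doc[["testdata"]] %||% list(),
                     provenance = unlist(doc[["provenance"]]) %||%
                       character(0L))
}
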