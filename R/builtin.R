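# Builtin format specifications shipped with the package, and the
# deterministic fixture-file generator used in examples and tests.

#' List the builtin format specifications
#'
#' @return character vector of builtin specification names.
#' @export
listBuiltinSpecs <- function() {
  dir_ <- system.file("extdata", "specs", package = "FlatFormats")
  sort(sub("\\.yaml$", "", list.files(dir_, pattern = "\\.yaml$")))
}

#' Path of a builtin specification file
#'
#' @param name one of [listBuiltinSpecs()].
#' @return path to the YAML specification.
#' @export
builtinSpecPath <- function(name) {
  stopifnot(isString(name))
  p <- system.file("extdata", "specs", paste0(name, ".yaml"),
                   package = "FlatFormats")
  if (!nzchar(p))
    tfError("flatformatsUsageError",
            sprintf("unknown builtin specification '%s' (available: %s)",
                    name, paste(listBuiltinSpecs(), collapse = ", ")))
  p
}

#' Load a builtin specification
#'
#' Builtins cover NCBI FASTA sequence identifiers (`ncbi_id`), sequence
#' database accessions (`accessions`), the tab-separated EGC expected
#' genomic content format (`egc`), FASTA (`fasta`), FASTQ (`fastq`), a
#' tabular assembly-graph subset with typed tags (`gfa_like`) and a
#' header/alignment two-section tabular subset (`sam_like`).
#'
#' @inheritParams builtinSpecPath
#' @return a [CompiledSpecification-class].
#' @examples
#' spec <- loadBuiltinSpec("ncbi_id")
#' decode("sp|P01013|OVAX_CHICK", spec, "ncbi_id")
#' @export
loadBuiltinSpec <- function(name) {
  loadSpecification(builtinSpecPath(name))
}

randomIdent <- function(len = 6L) {
  paste0(sample(c(letters, "_"), 1L),
         paste(sample(c(letters, as.character(0:9), "_"), len, replace = TRUE),
               collapse = ""))
}

randomSeq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

#' Generate a deterministic fixture file in a builtin format
#'
#' Produces a valid file of `nRecords` records in one of the builtin
#' formats; every generated file fully decodes under its builtin
#' specification.  EGC files mix the four record types and interleave
#' comment lines; FASTA/FASTQ files contain random sequences with valid
#' headers and qualities (FASTQ quality strings have the same length as
#' their sequence).
#'
#' @param format one of `"egc"`, `"fasta"`, `"fastq"`, `"gfa"`, `"sam"`.
#' @param nRecords number of records (EGC: data records; FASTA/FASTQ:
#'   entries; GFA: segment/link records after the header; SAM: alignment
#'   lines after the header section).
#' @param seed integer seed (same seed, same file).
#' @param path optional path; when given the lines are written there.
#' @return invisibly, a list with elements `lines` (character vector) and
#'   `counts` (named integer vector: the generator's own tally by record
#'   type).
#' @export
generateFixture <- function(format, nRecords, seed = 0L, path = NULL) {
  stopifnot(isString(format), isCount(nRecords))
  res <- withSeed(seed, switch(format,
    egc = fixtureEgc(nRecords),
    fasta = fixtureFasta(nRecords),
    fastq = fixtureFastq(nRecords),
    gfa = fixtureGfa(nRecords),
    sam = fixtureSam(nRecords),
    tfError("flatformatsUsageError",
            sprintf("unknown fixture format '%s'", format))))
  if (!is.null(path)) writeLines(res$lines, path)
  invisible(res)
}

fixtureEgc <- function(n) {
  lines <- character(0L)
  counts <- c(A = 0L, T = 0L, P = 0L, E = 0L, comment = 0L)
  subjects <- character(0L)
  attributes <- character(0L)
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  ops <- c("=", "<", ">", "<=", ">=", "in")
  for (i in seq_len(n)) {
    if (runif(1L) < 0.1) {
      lines <- c(lines, paste0("# ", randomIdent(8L)))
      counts[["comment"]] <- counts[["comment"]] + 1L
    }
    rt <- sample(c("A", "T", "P", "E"), 1L,
                 prob = c(0.25, 0.2, 0.15, 0.4))
    line <- switch(rt,
      A = {
        id <- randomIdent()
        attributes <- c(attributes, id)
        paste("A", id, paste0("attribute ", id),
              if (runif(1L) < 0.5) "." else paste0("count_", randomIdent(3L)),
              sep = "\t")
      },
      T = {
        id <- randomIdent()
        subjects <- c(subjects, id)
        paste("T", id, paste0("Taxon ", toupper(substr(id, 2L, 4L))),
              if (runif(1L) < 0.3) "." else sample(ranks, 1L), sep = "\t")
      },
      P = {
        id <- randomIdent()
        subjects <- c(subjects, id)
        paste("P", id, paste0("phenotype group ", id), sep = "\t")
      },
      E = {
        subj <- if (length(subjects)) sample(subjects, 1L) else randomIdent()
        attr_ <- if (length(attributes)) sample(attributes, 1L)
        else randomIdent()
        val <- if (runif(1L) < 0.2) "." else
          formatInt(sample.int(1000L, 1L))
        paste("E", subj, attr_, sample(ops, 1L), val, sep = "\t")
      })
    counts[[rt]] <- counts[[rt]] + 1L
    lines <- c(lines, line)
  }
  list(lines = lines, counts = counts)
}

fixtureFasta <- function(n) {
  lines <- character(0L)
  nseq <- 0L
  for (i in seq_len(n)) {
    lines <- c(lines, paste0(">seq", i, " length test ", i))
    k <- sample.int(3L, 1L)
    nseq <- nseq + k
    for (j in seq_len(k))
      lines <- c(lines, randomSeq(10L + sample.int(50L, 1L)))
  }
  list(lines = lines, counts = c(header = n, sequence = nseq))
}

fixtureFastq <- function(n) {
  lines <- character(0L)
  for (i in seq_len(n)) {
    len <- 20L + sample.int(30L, 1L)
    lines <- c(lines,
               paste0("@read", i),
               randomSeq(len),
               "+",
               paste(sample(strsplit(rawToChar(as.raw(33:73)), "")[[1L]],
                            len, replace = TRUE), collapse = ""))
  }
  list(lines = lines, counts = c(record = n))
}

fixtureGfa <- function(n) {
  lines <- "H\tVN:Z:1.0"
  counts <- c(H = 1L, S = 0L, L = 0L)
  segs <- character(0L)
  for (i in seq_len(n)) {
    if (length(segs) >= 2L && runif(1L) < 0.4) {
      ab <- sample(segs, 2L)
      lines <- c(lines, paste("L", ab[1L], sample(c("+", "-"), 1L),
                              ab[2L], sample(c("+", "-"), 1L),
                              paste0(sample.int(20L, 1L), "M"), sep = "\t"))
      counts[["L"]] <- counts[["L"]] + 1L
    } else {
      nm <- paste0("s", length(segs) + 1L)
      segs <- c(segs, nm)
      seq_ <- if (runif(1L) < 0.2) "*" else randomSeq(sample.int(40L, 1L))
      line <- paste("S", nm, seq_, sep = "\t")
      if (runif(1L) < 0.5 && seq_ != "*")
        line <- paste(line, paste0("LN:i:", nchar(seq_)), sep = "\t")
      lines <- c(lines, line)
      counts[["S"]] <- counts[["S"]] + 1L
    }
  }
  list(lines = lines, counts = counts)
}

fixtureSam <- function(n) {
  lines <- c("@HD\tVN:1.6", "@SQ\tSN:ref1\tLN:10000")
  for (i in seq_len(n)) {
    len <- 20L + sample.int(20L, 1L)
    line <- paste(paste0("read", i), sample(c(0L, 16L), 1L), "ref1",
                  sample.int(9000L, 1L), sample.int(60L, 1L),
                  randomSeq(len), sep = "\t")
    if (runif(1L) < 0.4)
      line <- paste(line, paste0("NM:i:", sample.int(5L, 1L) - 1L),
                    sep = "\t")
    lines <- c(lines, line)
  }
  list(lines = lines, counts = c(header = 2L, alignment = n))
}
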