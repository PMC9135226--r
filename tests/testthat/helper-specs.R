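# Helpers: in-code construction of small specifications and random trees.

specFromText <- function(text) loadSpecification(text)

writeSpecFile <- function(text, dir = tempdir()) {
  f <- tempfile(tmpdir = dir, fileext = ".yaml")
  writeLines(text, f)
  f
}

# random definition trees for fuzzing the tree validator (a mix of valid,
# invalid and nonsense structures)
randomTree <- function(depth = 2L) {
  pick <- sample.int(10L, 1L)
  if (depth <= 0L || pick <= 2L) {
    return(switch(sample.int(4L, 1L),
                  paste(sample(letters, 3L), collapse = ""),
                  sample.int(100L, 1L),
                  list(),
                  list("a", "b")))
  }
  keys <- sample(c("constant", "values", "integer", "list_of", "one_of",
                   "bogus", "prefix", "min_length", "regex"),
                 sample.int(3L, 1L))
  out <- list()
  for (k in keys) out[[k]] <- randomTree(depth - 1L)
  out
}

# the example identifier of every NCBI FASTA db tag
NCBI_EXAMPLES <- c(
  ref = "ref|NM_010450.1",    gb  = "gb|M73307|AGMA13GT",
  tpg = "tpg|BK003456|",      emb = "emb|CAM43271.1|",
  tpe = "tpe|BN000123|",      dbj = "dbj|BAC85684.1",
  tpd = "tpd|FAA00017|",      sp  = "sp|P01013|OVAX_CHICK",
  tr  = "tr|Q90RT2|Q90RT2_9HIV1", pir = "pir||G36364",
  pdb = "pdb|1I4L|D",         prf = "prf||0806162C",
  pat = "pat|US|RE33188|1",   pgp = "pgp|EP|0238993|7",
  gnl = "gnl|taxon|9606",     lcl = "lcl|hnm271",
  bbs = "bbs|316342",         bbm = "bbm|464147",
  gim = "gim|442187",         gi  = "gi|21434723",
  gpp = "gpp|GPC_123456789",  nat = "nat|AT_123456789.1|")

# independent brute-force recognizers (character-level, no regexes) used as
# oracles against isValidEncoded
chrs <- function(s) strsplit(s, "")[[1L]]
DIGITS <- as.character(0:9)
LETTERS_ALL <- c(LETTERS, letters)

oracleIdentifier <- function(s) {
  cs <- chrs(s)
  if (!length(cs)) return(FALSE)
  if (!(cs[1L] %in% c(LETTERS_ALL, "_"))) return(FALSE)
  all(cs %in% c(LETTERS_ALL, DIGITS, "_"))
}

oracleMissing <- function(s) identical(s, ".")

oracleIdField <- function(s) {
  all(chrs(s) %in% c(LETTERS_ALL, DIGITS, "_", "."))
}

oracleMapq <- function(s) {
  cs <- chrs(s)
  if (!length(cs)) return(FALSE)
  if (!all(cs %in% DIGITS)) return(FALSE)
  as.numeric(s) <= 255
}

# any non-empty tab-free string: either the missing marker "." or free text
oracleMaybeText <- function(s) {
  nchar(s) >= 1L && !any(chrs(s) == "\t")
}

# all strings of length <= n over an alphabet
enumerateStrings <- function(alphabet, n) {
  out <- ""
  level <- ""
  for (i in seq_len(n)) {
    level <- as.vector(outer(level, alphabet, paste0))
    out <- c(out, level)
  }
  out
}

# path-enumeration oracle for cycle detection: a directed graph has a cycle
# iff some node reaches itself (transitive closure by repeated squaring)
oracleHasCycle <- function(nodes, edges) {
  n <- length(nodes)
  if (n == 0L) return(FALSE)
  m <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges)))
    m[edges$from[i], edges$to[i]] <- TRUE
  reach <- m
  for (k in seq_len(n)) reach <- reach | (reach %*% m > 0)
  any(diag(reach))
}

randomGraph <- function(nNodes, pEdge = 0.25) {
  nodes <- paste0("n", seq_len(nNodes))
  pairs <- expand.grid(from = nodes, to = nodes,
                       stringsAsFactors = FALSE)
  keep <- runif(nrow(pairs)) < pEdge
  list(nodes = nodes, edges = pairs[keep, , drop = FALSE])
}
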