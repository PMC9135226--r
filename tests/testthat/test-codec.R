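roman <- function() loadSpecification(paste(
  "datatypes:",
  "  roman: {regexes: ['III', 'II', 'I'],",
  "          decoded: {'I': 1, 'II': 2, 'III': 3}}", sep = "\n"))

test_that("transformation maps decode symbols to values and back", {
  s <- roman()
  expect_identical(decode("III", s, "roman"), 3L)
  expect_identical(decode("I", s, "roman"), 1L)
  expect_identical(encode(3, s, "roman"), "III")
  expect_identical(encode(1L, s, "roman"), "I")

  d <- loadSpecification(
    "datatypes: {cigarop: {values: ['D', 'I'], decoded: {'D': 'deletion', 'I': 'insertion'}}}")
  expect_identical(decode("D", d, "cigarop"), "deletion")
  expect_identical(encode("deletion", d, "cigarop"), "D")
})

test_that("non-injective decoded maps encode to the first-listed text", {
  s <- loadSpecification(paste(
    "datatypes:",
    "  b: {values: ['T', 'true', 'F'],",
    "      decoded: {'T': true, 'true': true, 'F': false}}", sep = "\n"))
  expect_identical(decode("true", s, "b"), TRUE)
  expect_identical(encode(TRUE, s, "b"), "T")
  # a canonical rule picks a different representative
  s2 <- loadSpecification(paste(
    "datatypes:",
    "  b: {values: ['T', 'true', 'F'],",
    "      decoded: {'T': true, 'true': true, 'F': false},",
    "      canonical: {'true': 'true'}}", sep = "\n"))
  expect_identical(encode(TRUE, s2, "b"), "true")
})

test_that("empty-text rules represent a designated value as the empty string", {
  s <- loadSpecification(paste(
    "datatypes:",
    "  xs: {list_of: {regex: '[a-z]+'}, min_length: 0,",
    "       splitted_by: \"\\t\", empty: ~}", sep = "\n"))
  expect_identical(encode(list(), s, "xs"), "")
  expect_null(decode("", s, "xs"))
  expect_identical(decode("ab\tcd", s, "xs"), list("ab", "cd"))
})

test_that("prefixes and suffixes are required, stripped and re-added", {
  s <- loadSpecification(
    "datatypes: {h: {regex: '[a-z]+', prefix: '>', suffix: '!'}}")
  expect_identical(decode(">abc!", s, "h"), "abc")
  expect_error(decode("abc!", s, "h"), class = "flatformatsDecodeError")
  expect_error(decode(">abc", s, "h"), class = "flatformatsDecodeError")
  expect_identical(encode("abc", s, "h"), ">abc!")
})

test_that("composed_of decodes to a field-keyed mapping, lists to sequences", {
  spec <- loadBuiltinSpec("ncbi_id")
  expect_identical(decode("gi|21434723", spec, "ncbi_id"),
                   list(db_tag = "gi", fields = list("21434723")))
  v <- decode("sp|P01013|OVAX_CHICK", spec, "ncbi_id")
  expect_identical(v$db_tag, "sp")
  expect_identical(v$fields, list("P01013", "OVAX_CHICK"))
})

test_that("trailing optional fields may be absent but not middle ones", {
  s <- loadSpecification(paste(
    "datatypes:",
    "  r: {composed_of: [{a: {regex: '[0-9]'}}, {b: {regex: '[0-9]'}},",
    "      {c: {regex: '[0-9]'}}], n_required: 1, splitted_by: ':'}",
    sep = "\n"))
  expect_identical(decode("1", s, "r"), list(a = "1"))
  expect_identical(decode("1:2", s, "r"), list(a = "1", b = "2"))
  expect_identical(encode(list(a = "1", b = "2"), s, "r"), "1:2")
  expect_error(encode(list(a = "1", c = "3"), s, "r"),
               class = "flatformatsEncodeError")
  expect_error(decode("1:2:3:4", s, "r"), class = "flatformatsDecodeError")
})

test_that("non-exclusive separators parse with backtracking", {
  # the separator ':' also occurs inside the second field
  s <- loadSpecification(paste(
    "datatypes:",
    "  r: {composed_of: [{a: {regex: '[0-9]+'}},",
    "      {b: {regex: '[0-9:]+'}}], separator: ':'}", sep = "\n"))
  expect_identical(decode("12:3:4", s, "r"), list(a = "12", b = "3:4"))
  l <- loadSpecification(paste(
    "datatypes:",
    "  l: {list_of: {regex: '[0-9]+'}, separator: ','}", sep = "\n"))
  expect_identical(decode("1,22,333", l, "l"), list("1", "22", "333"))
})

test_that("labeled lists enforce label sets, duplicates and required labels", {
  s <- loadSpecification(paste(
    "datatypes:",
    "  ll: {labeled_list: {x: {integer: {}}, y: {regex: '[a-z]+'}},",
    "       required: [x], splitted_by: ';'}", sep = "\n"))
  expect_identical(decode("x:4;y:ab", s, "ll"), list(x = 4L, y = "ab"))
  expect_identical(decode("y:ab;x:4", s, "ll"), list(y = "ab", x = 4L))
  expect_error(decode("y:ab", s, "ll"), "required")
  expect_error(decode("x:1;x:2", s, "ll"), "duplicated")
  expect_error(decode("z:1;x:2", s, "ll"), "unknown label")
  expect_identical(encode(list(x = 7L), s, "ll"), "x:7")
  expect_error(encode(list(y = "ab"), s, "ll"),
               class = "flatformatsEncodeError")
})

test_that("tagged lists select the value datatype by type code", {
  spec <- loadBuiltinSpec("gfa_like")
  v <- decode("LN:i:42\tVN:Z:1.0", spec, "tags")
  expect_identical(v, list(LN = 42L, VN = "1.0"))
  expect_identical(encode(v, spec, "tags"), "LN:i:42\tVN:Z:1.0")
  expect_error(decode("LN:q:42", spec, "tags"), "unknown tag type code")
  expect_error(decode("LN:i:4\tLN:i:5", spec, "tags"), "duplicated tag")
})

test_that("validation mirrors decode/encode success", {
  spec <- loadBuiltinSpec("ncbi_id")
  expect_true(isValidEncoded("pdb|1I4L|D", spec, "ncbi_id"))
  expect_false(isValidEncoded("xy|123", spec, "ncbi_id"))
  expect_true(isValidDecoded(list(db_tag = "gi", fields = list("1")),
                             spec, "ncbi_id"))
  expect_false(isValidDecoded(list(db_tag = "zz", fields = list("1")),
                              spec, "ncbi_id"))
})

test_that("round trips hold on randomized corpora across builtin specs", {
  for (name in c("egc", "gfa_like", "ncbi_id", "accessions")) {
    spec <- loadBuiltinSpec(name)
    for (dt in datatypeNames(spec)) {
      td <- tryCatch(
        generateExamples(spec, dt, nValid = 12L, nInvalid = 0L, seed = 99L),
        flatformatsUnsatisfiable = function(e) NULL)
      if (is.null(td)) next
      for (pair in td$valid) {
        # value round trip: decode(encode(v)) == v
        re <- encode(pair$value, spec, dt)
        expect_true(FlatFormats:::dvEqual(decode(re, spec, dt), pair$value),
                    label = sprintf("%s/%s value round trip on %s",
                                    name, dt, deparse(pair$text)))
        # text round trip (semantic): encode(decode(t)) decodes to same value
        expect_true(FlatFormats:::dvEqual(
          decode(encode(decode(pair$text, spec, dt), spec, dt), spec, dt),
          decode(pair$text, spec, dt)),
          label = sprintf("%s/%s text round trip on %s",
                          name, dt, deparse(pair$text)))
      }
    }
  }
})

test_that("decode errors carry a path and an in-range offset", {
  spec <- loadBuiltinSpec("egc")
  bad <- "E\tbacillus\tgc\t~~\t40"
  err <- tryCatch(decode(bad, spec, "record_E"), error = function(e) e)
  expect_s3_class(err, "flatformatsDecodeError")
  expect_true(err$offset >= 1L && err$offset <= nchar(bad))
  # the offset points at the start of the failing operator field
  expect_identical(err$offset, as.integer(regexpr("~~", bad, fixed = TRUE)))
  expect_true("operator" %in% err$path)

  err2 <- tryCatch(decode("E\tbacillus", spec, "record_E"),
                   error = function(e) e)
  expect_match(conditionMessage(err2), "missing required field")
})

test_that("numeric fidelity: integers exact, floats round-trip-safe", {
  s <- loadSpecification(paste(
    "datatypes:",
    "  i: {integer: {}}",
    "  f: {float: {}}", sep = "\n"))
  expect_identical(decode("2147483646", s, "i"), 2147483646L)
  expect_identical(decode("9007199254740992", s, "i"), 9007199254740992)
  for (x in c(0.1, 1/3, 1e-12, 123456.789, -2.5e8)) {
    expect_identical(decode(encode(x, s, "f"), s, "f"), x)
  }
})
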