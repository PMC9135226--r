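test_that("constant matchers are anchored escaped literals", {
  d <- normalizeDefinition("ACGT", "motif")
  m <- compileMatcher(d)
  expect_true(grepl(m$pattern, "ACGT", perl = TRUE))
  expect_false(grepl(m$pattern, "ACGTT", perl = TRUE))
  expect_false(grepl(m$pattern, "xACGT", perl = TRUE))
})

test_that("literals containing regex metacharacters never change the language", {
  metas <- c("a.b", "x|y", "p*q", "w+z", "(k)", "[m]", "{2}", "a\\b", "c$d^e")
  for (lit in metas) {
    d <- normalizeDefinition(list(constant = lit), "lit")
    expect_true(isValidEncoded(lit, d))
    expect_false(isValidEncoded(paste0(lit, "!"), d))
    expect_false(isValidEncoded(paste0("Q", lit), d))
    # separators too
    l <- normalizeDefinition(
      list(list_of = list(values = list("1", "2")), length = 2,
           splitted_by = lit), "l")
    expect_true(isValidEncoded(paste("1", "2", sep = lit), l))
    expect_false(isValidEncoded("12", l))
  }
})

test_that("base-16 unsigned integers accept optional radix prefixes", {
  spec <- loadSpecification(
    "datatypes: {u: {unsigned_integer: {base: 16, max: 255}}}")
  expect_true(isValidEncoded("FF", spec, "u"))
  expect_true(isValidEncoded("0xFF", spec, "u"))
  expect_false(isValidEncoded("FG", spec, "u"))
  expect_identical(decode("0xff", spec, "u"), 255L)
  # canonical encoding omits the prefix unless the prefix rule is set
  expect_equal(encode(255, spec, "u"), "FF")
  spec2 <- loadSpecification(
    "datatypes: {u: {unsigned_integer: {base: 16, max: 255, prefix: true}}}")
  expect_equal(encode(255, spec2, "u"), "0xFF")
})

test_that("integer validation agrees with a direct range test on -10..300", {
  spec <- loadSpecification(
    "datatypes: {byte: {integer: {min: 0, max: 255}}}")
  for (i in -10:300) {
    expect_identical(isValidEncoded(formatC(i, format = "d"), spec, "byte"),
                     i >= 0 && i <= 255)
  }
})

test_that("open float bounds exclude the boundary in the derived regex check", {
  spec <- loadSpecification(
    "datatypes: {f: {float: {min: 0, max: 1, min_excluded: true}}}")
  expect_false(isValidEncoded("0", spec, "f"))
  expect_false(isValidEncoded("0.0", spec, "f"))
  expect_true(isValidEncoded("0.1", spec, "f"))
  expect_true(isValidEncoded("1", spec, "f"))
  expect_true(isValidEncoded("1e-3", spec, "f"))
})

test_that("value-set matchers accept exactly the members", {
  d <- normalizeDefinition(list(values = list("+", "-")), "sign")
  pat <- deriveValueRegex(d)
  for (s in c("+", "-")) expect_true(grepl(pat, s, perl = TRUE))
  for (s in c("", "+-", "x", "++")) expect_false(grepl(pat, s, perl = TRUE))
})

test_that("one_of attributes a parse to the earlier alternative", {
  spec <- loadSpecification(paste(
    "datatypes:",
    "  amb:",
    "    one_of:",
    "      - {regex: '[0-9]+', decoded: {'1': 'from-first'}}",
    "      - {regex: '[0-9]', decoded: {'1': 'from-second'}}", sep = "\n"))
  expect_identical(decode("1", spec, "amb"), "from-first")
})

test_that("matcher acceptance equals decoder success on random corpora", {
  set.seed(11)
  specs <- list(
    loadSpecification("datatypes: {t: {list_of: {values: ['ab', 'c']},
                                       min_length: 0, splitted_by: ','}}"),
    loadSpecification("datatypes: {t: {composed_of: [{a: {regex: '[xy]+'}},
      {b: {values: ['1','2']}}], n_required: 1, splitted_by: ':'}}"),
    loadSpecification("datatypes: {t: {one_of: [{constant: '*'},
      {regex: '[A-Z]{2,3}'}]}}"))
  alphabet <- c("a", "b", "c", "x", "y", "1", "2", ",", ":", "*", "A", "B")
  for (spec in specs) {
    m <- spec@matchers[["t"]]
    for (i in 1:400) {
      s <- paste(sample(alphabet, sample.int(6L, 1L), replace = TRUE),
                 collapse = "")
      regexSays <- grepl(m$pattern, s, perl = TRUE)
      decodeSays <- !inherits(
        tryCatch(decode(s, spec, "t"), error = function(e) e), "error")
      expect_identical(regexSays, decodeSays, label = sprintf(
        "agreement on %s", deparse(s)))
    }
  }
})

test_that("invalid user regexes and over-complex patterns are rejected", {
  expect_error(loadSpecification("datatypes: {r: {regex: '[unclosed'}}"),
               class = "flatformatsSyntaxError")
  d <- normalizeDefinition(
    list(regex = paste(rep("(a)", 60L), collapse = "")), "many")
  expect_error(compileMatcher(d, groupCap = 50L),
               class = "flatformatsPatternTooComplex")
})

test_that("compiled matchers report their parsing strategy", {
  spec <- loadSpecification(paste(
    "datatypes:",
    "  s: {list_of: {regex: '[a-z]'}, splitted_by: ','}",
    "  r: {list_of: {regex: '[a-z]'}, separator: ','}",
    "  k: {constant: 'x'}", sep = "\n"))
  expect_equal(spec@matchers[["s"]]$strategy, "split")
  expect_equal(spec@matchers[["r"]]$strategy, "regex")
  expect_equal(spec@matchers[["k"]]$strategy, "regex")
})
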