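test_that("embedded testdata execution aggregates passes and failures", {
  spec <- loadSpecification(paste(
    "datatypes:",
    "  b: {values: ['T', 'F'], decoded: {'T': true, 'F': false}}",
    "testdata:",
    "  b:",
    "    valid: {'T': true, 'F': false}",
    "    invalid: ['X', '']", sep = "\n"))
  rep <- runTestdata(spec)
  expect_s4_class(rep, "TestReport")
  expect_identical(rep@passed, 4L)
  expect_identical(rep@failed, 0L)
})

test_that("wrong expectations are reported, not swallowed", {
  spec <- loadSpecification(paste(
    "datatypes:",
    "  n: {integer: {min: 0, max: 5}}",
    "testdata:",
    "  n:",
    "    valid: {'3': 4}",
    "    invalid: ['2']", sep = "\n"))
  rep <- runTestdata(spec)
  expect_identical(rep@failed, 2L)
  expect_setequal(rep@failures$direction, c("decode", "validate-encoded"))
})

test_that("testdata referencing unknown datatypes is an error", {
  spec <- loadSpecification("datatypes: {x: {constant: 'A'}}")
  expect_error(runTestdata(spec, list(nosuch = list(valid = list("A")))),
               class = "flatformatsUnknownDatatype")
})

test_that("testdata can live in a separate file with the same grammar", {
  spec <- loadSpecification("datatypes: {x: {values: ['A', 'B']}}")
  tf <- writeSpecFile(paste(
    "testdata:",
    "  x:",
    "    valid: ['A', 'B']",
    "    invalid: ['C']", sep = "\n"))
  rep <- runTestdata(spec, tf)
  expect_identical(rep@passed, 3L)
  expect_identical(rep@failed, 0L)
})

test_that("generated examples include interval boundaries and members", {
  spec <- loadSpecification("datatypes: {n: {integer: {min: 0, max: 10}}}")
  td <- generateExamples(spec, "n", nValid = 3L, nInvalid = 2L, seed = 1L)
  texts <- vapply(td$valid, `[[`, character(1L), "text")
  expect_true(all(c("0", "10") %in% texts))
  expect_true(all(c("-1", "11") %in% td$invalid_encoded))

  spec2 <- loadSpecification("datatypes: {k: {constant: 'A'}}")
  td2 <- generateExamples(spec2, "k", nValid = 1L, nInvalid = 1L, seed = 0L)
  expect_identical(vapply(td2$valid, `[[`, character(1L), "text"), "A")
})

test_that("generation is deterministic given the seed", {
  spec <- loadBuiltinSpec("egc")
  a <- generateExamples(spec, "line", nValid = 20L, nInvalid = 5L, seed = 3L)
  b <- generateExamples(spec, "line", nValid = 20L, nInvalid = 5L, seed = 3L)
  expect_identical(a, b)
  c_ <- generateExamples(spec, "line", nValid = 20L, nInvalid = 5L, seed = 4L)
  expect_false(identical(a, c_))
})

test_that("generated examples are sound for every builtin datatype", {
  for (name in listBuiltinSpecs()) {
    spec <- loadBuiltinSpec(name)
    for (dt in datatypeNames(spec)) {
      td <- tryCatch(
        generateExamples(spec, dt, nValid = 4L, nInvalid = 2L, seed = 0L),
        flatformatsUnsatisfiable = function(e)
          generateExamples(spec, dt, nValid = 4L, nInvalid = 0L, seed = 0L))
      for (pair in td$valid)
        expect_true(isValidEncoded(pair$text, spec, dt),
                    label = sprintf("%s/%s valid %s", name, dt,
                                    deparse(pair$text)))
      for (bad in td$invalid_encoded)
        expect_false(isValidEncoded(bad, spec, dt),
                     label = sprintf("%s/%s invalid %s", name, dt,
                                     deparse(bad)))
      for (v in td$invalid_decoded)
        expect_false(isValidDecoded(v, spec, dt))
    }
  }
})

test_that("generator output fed back to the test runner passes in full", {
  spec <- loadBuiltinSpec("gfa_like")
  for (dt in c("segment_line", "tags", "line")) {
    td <- generateExamples(spec, dt, nValid = 10L, nInvalid = 3L, seed = 2L)
    rep <- runTestdata(spec, td)
    expect_identical(rep@failed, 0L)
    expect_gt(rep@passed, 0L)
  }
})

test_that("an all-accepting datatype cannot yield invalid examples", {
  spec <- loadSpecification("datatypes: {any: {regex: '.*'}}")
  expect_error(generateExamples(spec, "any", nValid = 1L, nInvalid = 1L),
               class = "flatformatsUnsatisfiable")
  # but zero requested invalids is fine
  td <- generateExamples(spec, "any", nValid = 2L, nInvalid = 0L)
  expect_length(td$invalid_encoded, 0L)
})

test_that("regex-directed synthesis covers the documented pattern subset", {
  pats <- c("[A-Z]{2,4}[0-9]+", "a|bb|ccc", "x(yz)?", "\\d{3}-\\d{2}",
            "[^0-9\\t]+", "(ab)+c*", "A\\.B")
  set.seed(1)
  for (p in pats) {
    for (i in 1:10) {
      s <- FlatFormats:::synthesizeFromRegex(p)
      expect_true(grepl(paste0("^(?:", p, ")$"), s, perl = TRUE),
                  label = sprintf("'%s' matches '%s'", s, p))
    }
  }
  expect_error(FlatFormats:::synthesizeFromRegex("(?=look)ahead"),
               class = "flatformatsUnsatisfiable")
})
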