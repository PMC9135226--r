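test_that("a minimal document loads into a one-datatype specification", {
  spec <- loadSpecification("datatypes: {x: {constant: 'A'}}")
  expect_s4_class(spec, "CompiledSpecification")
  expect_equal(datatypeNames(spec), "x")
  expect_equal(decode("A", spec, "x"), "A")
})

test_that("unknown sections and bad names are rejected", {
  expect_error(loadSpecification("datatypes: {x: {constant: 'A'}}\nextra: 1"),
               class = "flatformatsSyntaxError")
  expect_error(loadSpecification("datatypes: {'1x': {constant: 'A'}}"),
               class = "flatformatsSyntaxError")
  expect_error(loadSpecification("datatypes: {x: {constant: 'A', bogus: 1}}"),
               class = "flatformatsSyntaxError")
})

test_that("JSON documents load like YAML documents", {
  y <- loadSpecification("datatypes: {n: {integer: {min: 0, max: 9}}}")
  j <- loadSpecification('{"datatypes": {"n": {"integer": {"min": 0, "max": 9}}}}')
  expect_equal(datatypeNames(y), datatypeNames(j))
  expect_identical(decode("7", y, "n"), decode("7", j, "n"))
})

test_that("unresolved and circular references are detected at load", {
  expect_error(loadSpecification("datatypes: {a: {list_of: missing}}"),
               class = "flatformatsUnresolvedReference")
  err <- tryCatch(
    loadSpecification("datatypes: {a: {list_of: b}, b: {list_of: a}}"),
    error = function(e) e)
  expect_s3_class(err, "flatformatsCycleError")
  expect_match(conditionMessage(err), "a -> b -> a")
  expect_error(loadSpecification("datatypes: {a: {list_of: a}}"),
               class = "flatformatsCycleError")
})

test_that("includes merge datatypes and namespaces rename them", {
  inc <- writeSpecFile(paste(
    "namespace: gfa",
    "datatypes:",
    "  tag: {regex: '[A-Z]+'}",
    "  pair: {list_of: tag, length: 2, splitted_by: ','}", sep = "\n"))
  main <- writeSpecFile(sprintf(paste(
    "include: ['%s']",
    "datatypes:",
    "  mine: {list_of: 'gfa::pair', splitted_by: ';'}", sep = "\n"), inc))
  spec <- loadSpecification(main)
  expect_setequal(datatypeNames(spec), c("gfa::tag", "gfa::pair", "mine"))
  # internal references were rewritten to the namespaced names
  expect_equal(decode("AB,CD;EF,GH", spec, "mine"),
               list(list("AB", "CD"), list("EF", "GH")))
})

test_that("include whitelists import only the named datatypes (plus deps)", {
  inc <- writeSpecFile(paste(
    "datatypes:",
    "  x: {constant: 'X'}",
    "  y: {constant: 'Y'}", sep = "\n"))
  spec <- loadSpecification(sprintf(
    "include:\n  - path: '%s'\n    datatypes: [x]", inc))
  expect_equal(datatypeNames(spec), "x")

  # a whitelisted datatype drags in its transitive dependencies
  inc2 <- writeSpecFile(paste(
    "datatypes:",
    "  lst: {list_of: elem, splitted_by: ','}",
    "  elem: {regex: '[a-z]+'}",
    "  unused: {constant: 'U'}", sep = "\n"))
  spec2 <- loadSpecification(sprintf(
    "include:\n  - path: '%s'\n    datatypes: [lst]", inc2))
  expect_setequal(datatypeNames(spec2), c("lst", "elem"))
})

test_that("include cycles across files are detected", {
  a <- tempfile(fileext = ".yaml")
  b <- tempfile(fileext = ".yaml")
  writeLines(sprintf("include: ['%s']\ndatatypes: {a1: {constant: 'a'}}", b), a)
  writeLines(sprintf("include: ['%s']\ndatatypes: {b1: {constant: 'b'}}", a), b)
  expect_error(loadSpecification(a), class = "flatformatsIncludeCycle")
  expect_error(loadSpecification(a), "include cycle")
})

test_that("including the same file through two paths yields one copy", {
  base <- writeSpecFile("datatypes: {shared: {constant: 'S'}}")
  mid <- writeSpecFile(sprintf(
    "include: ['%s']\ndatatypes: {m: {list_of: shared, splitted_by: ','}}",
    base))
  spec <- loadSpecification(sprintf(
    "include: ['%s', '%s']", base, mid))
  expect_setequal(datatypeNames(spec), c("shared", "m"))
})

test_that("colliding definitions without namespace are an error", {
  a <- writeSpecFile("datatypes: {x: {constant: 'A'}}")
  expect_error(
    loadSpecification(sprintf(
      "include: ['%s']\ndatatypes: {x: {constant: 'B'}}", a)),
    class = "flatformatsNameCollision")
})

test_that("overrides replace sub-components of imported definitions", {
  inc <- writeSpecFile(paste(
    "datatypes:",
    "  code: {values: ['A', 'B']}", sep = "\n"))
  spec <- loadSpecification(sprintf(paste(
    "include:",
    "  - path: '%s'",
    "    override:",
    "      code: {values: ['A', 'B', 'C']}", sep = "\n"), inc))
  expect_true(isValidEncoded("C", spec, "code"))

  expect_error(loadSpecification(sprintf(paste(
    "include:",
    "  - path: '%s'",
    "    override:",
    "      nosuch: {values: ['A']}", sep = "\n"), inc)),
    class = "flatformatsOverrideError")
})

test_that("missing include files are reported", {
  expect_error(loadSpecification("include: ['/nonexistent/no.yaml']"),
               class = "flatformatsMissingInclude")
})

test_that("cycle check agrees with a path-enumeration oracle", {
  # fixed shapes
  expect_silent(checkAcyclic(list(
    nodes = c("a", "b", "c"),
    edges = data.frame(from = c("a", "b"), to = c("b", "c")))))
  err <- tryCatch(checkAcyclic(list(
    nodes = "a", edges = data.frame(from = "a", to = "a"))),
    error = function(e) e)
  expect_s3_class(err, "flatformatsCycleError")
  expect_equal(err$cycle, c("a", "a"))
  # randomized graphs vs transitive-closure oracle
  set.seed(7)
  for (i in 1:50) {
    g <- randomGraph(sample(2:8, 1L))
    expected <- oracleHasCycle(g$nodes, g$edges)
    got <- tryCatch({ checkAcyclic(g); FALSE },
                    flatformatsCycleError = function(e) TRUE)
    expect_identical(got, expected)
  }
})

test_that("dependency graphs track references through inline definitions", {
  spec <- loadSpecification(paste(
    "datatypes:",
    "  a: {list_of: {one_of: [b, {constant: 'k'}]}, splitted_by: ','}",
    "  b: {regex: '[0-9]'}", sep = "\n"))
  g <- dependencyGraph(spec)
  expect_setequal(g$nodes, c("a", "b"))
  expect_equal(g$edges$from, "a")
  expect_equal(g$edges$to, "b")
})

test_that("pre-compiled archives round-trip behaviourally", {
  spec <- loadBuiltinSpec("egc")
  arc <- tempfile(fileext = ".json")
  saveCompiled(spec, arc)
  spec2 <- loadSpecification(arc)   # auto-detected as an archive
  expect_identical(datatypeNames(spec), datatypeNames(spec2))
  line <- "E\tbacillus\tgc_content\t>=\t40"
  expect_identical(decode(line, spec, "line"), decode(line, spec2, "line"))
  expect_identical(encode(decode(line, spec2, "line"), spec2, "line"), line)
})

test_that("corrupt and mismatched archives are rejected", {
  spec <- loadSpecification("datatypes: {x: {constant: 'A'}}")
  arc <- tempfile(fileext = ".json")
  saveCompiled(spec, arc)
  truncated <- tempfile(fileext = ".json")
  full <- paste(readLines(arc), collapse = "\n")
  writeLines(substr(full, 1L, nchar(full) %/% 3L), truncated)
  expect_error(loadCompiled(truncated), class = "flatformatsCorruptArchive")
  expect_error(loadCompiled(writeSpecFile("datatypes: {}")),
               class = "flatformatsCorruptArchive")
  bad <- tempfile(fileext = ".json")
  writeLines(sub('"1.0"', '"0.0"', full, fixed = TRUE), bad)
  expect_error(loadCompiled(bad), class = "flatformatsVersionMismatch")
})
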