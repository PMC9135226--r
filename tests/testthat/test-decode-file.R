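test_that("line scope yields one record per line with spans", {
  f <- tempfile()
  writeLines(c("A\tgc\tGC content\t.",
               "A\tlen\tgenome length\tassembly_stat",
               "A\tcds\tCDS count\t."), f)
  spec <- loadBuiltinSpec("egc")
  recs <- decodeFile(f, spec, "record_A")
  expect_length(recs, 3L)
  expect_identical(recs[[2]]$span, c(2L, 2L))
  expect_identical(recs[[2]]$value$id, "len")
})

test_that("comment lines decode through the line one_of alternative", {
  f <- tempfile()
  writeLines(c("#x", "A\tgc\tGC content\t.", "# another comment"), f)
  spec <- loadBuiltinSpec("egc")
  recs <- decodeFile(f, spec, "line")
  expect_length(recs, 3L)
  expect_identical(recs[[1]]$value, "#x")
  expect_identical(recs[[2]]$value$record_type, "A")
})

test_that("line-scope errors carry the line number", {
  f <- tempfile()
  writeLines(c("A\tgc\tGC content\t.", "Z\tbroken"), f)
  spec <- loadBuiltinSpec("egc")
  err <- tryCatch(decodeFile(f, spec, "line"), error = function(e) e)
  expect_s3_class(err, "flatformatsDecodeError")
  expect_identical(err$line, 2L)
})

test_that("unit scope groups a fixed number of lines per record", {
  f <- tempfile()
  generateFixture("fastq", 3, seed = 5, path = f)
  spec <- loadBuiltinSpec("fastq")
  recs <- decodeFile(f, spec, "record")
  expect_length(recs, 3L)
  expect_identical(recs[[1]]$span, c(1L, 4L))
  expect_named(recs[[1]]$value, c("header", "sequence", "plus", "quality"))
  # a file whose line count is not a multiple of the unit size is an error
  f2 <- tempfile()
  writeLines(readLines(f)[1:6], f2)
  expect_error(decodeFile(f2, spec, "record"),
               class = "flatformatsStructuralError")
})

test_that("section scope spans maximal runs of matching lines", {
  f <- tempfile()
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:ref1\tLN:5"), f)
  spec <- loadBuiltinSpec("sam_like")
  recs <- decodeFile(f, spec, "header_section", scope = "section")
  expect_length(recs, 1L)
  expect_identical(recs[[1]]$span, c(1L, 2L))
  expect_length(recs[[1]]$value, 2L)
  # a line that cannot start a new section is an error under section scope
  f2 <- tempfile()
  writeLines(c("@HD\tVN:1.6", "r1\t0\tref1\t1\t60\tACGT"), f2)
  expect_error(decodeFile(f2, spec, "header_section", scope = "section"),
               class = "flatformatsStructuralError")
})

test_that("file scope validates global section structure", {
  spec <- loadBuiltinSpec("sam_like")
  f <- tempfile()
  generateFixture("sam", 10, seed = 2, path = f)
  recs <- decodeFile(f, spec, "file")
  expect_length(recs, 1L)
  expect_named(recs[[1]]$value, c("header", "alignments"))
  expect_length(recs[[1]]$value$alignments, 10L)

  # alignment line before the required header section
  f2 <- tempfile()
  writeLines(c("r1\t0\tref1\t1\t60\tACGT", "@HD\tVN:1.6"), f2)
  err <- tryCatch(decodeFile(f2, spec, "file"), error = function(e) e)
  expect_s3_class(err, "flatformatsStructuralError")
  expect_identical(err$line, 1L)

  # trailing line that belongs to no section
  f3 <- tempfile()
  writeLines(c("@HD\tVN:1.6", "r1\t0\tref1\t1\t60\tACGT", "@@@"), f3)
  expect_error(decodeFile(f3, spec, "file"),
               class = "flatformatsStructuralError")
})

test_that("streaming emits per-line records equivalent to whole-file decoding", {
  spec <- loadBuiltinSpec("sam_like")
  f <- tempfile()
  generateFixture("sam", 25, seed = 9, path = f)
  whole <- decodeFile(f, spec, "file")
  strm <- decodeFile(f, spec, "file", streaming = TRUE)
  flat <- c(whole[[1]]$value$header, whole[[1]]$value$alignments)
  expect_length(strm, length(flat))
  for (i in seq_along(flat))
    expect_identical(strm[[i]]$value, flat[[i]])
  expect_identical(unique(vapply(strm, `[[`, character(1L), "datatype")),
                   c("header", "alignments"))
  # spans increase monotonically across the stream
  startsAt <- vapply(strm, function(r) r$span[1L], integer(1L))
  expect_true(all(diff(startsAt) > 0L))
})

test_that("streaming still rejects structurally invalid files", {
  spec <- loadBuiltinSpec("sam_like")
  f <- tempfile()
  writeLines(c("r1\t0\tref1\t1\t60\tACGT"), f)
  expect_error(decodeFile(f, spec, "file", streaming = TRUE),
               class = "flatformatsStructuralError")
})

test_that("the record callback sees every record as it is produced", {
  spec <- loadBuiltinSpec("egc")
  f <- tempfile()
  generateFixture("egc", 20, seed = 4, path = f)
  seen <- 0L
  recs <- decodeFile(f, spec, "line",
                     callback = function(r) seen <<- seen + 1L)
  expect_identical(seen, length(recs))
})

test_that("empty files decode to zero records under line scope", {
  f <- tempfile()
  writeLines(character(0L), f)
  spec <- loadBuiltinSpec("egc")
  expect_length(decodeFile(f, spec, "line"), 0L)
})
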