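test_that("a clamped domain releases zero contour", {
  d <- FoldableDomain("R8", 124, 40.14, 0.06, 1.5, clamped = TRUE,
                      clampSpan = 124)
  expect_identical(releasedLength(d), 0)
  expect_equal(releasedLength(FoldableDomain("R8", 124, 40.14, 0.06, 1.5)),
               40.14)
})

test_that("domain validity catches inconsistent clamp spans and parameters", {
  expect_error(FoldableDomain("X", 50, 20, 0.1, 1, clamped = TRUE,
                              clampSpan = 60), "clampSpan")
  expect_error(FoldableDomain("X", 50, -2, 0.1, 1), "deltaLc")
  expect_error(FoldableDomain("X", 50, 20, 0, 1), "Bell")
})

test_that("construct contour bookkeeping adds handle, folded sizes and releases", {
  wt <- talinR7R8Construct()
  cl <- talinR7R8Construct(clamped = TRUE)
  folded <- 30 + 4 * 4.5
  expect_equal(foldedContour(wt), folded)
  expect_equal(foldedContour(cl), folded)
  r8 <- residuesToContourGain(124, 0.36, 4.5)
  expect_equal(releasableContour(wt) - releasableContour(cl), r8)
  expect_equal(releasableContour(wt), 2 * 28 + 63.9 + r8)
  expect_error(PolyproteinConstruct(list(
    FoldableDomain("A", 10, 5, 1, 1), FoldableDomain("A", 10, 5, 1, 1))),
    "unique")
})

test_that("construct definitions round-trip through the structured-text format", {
  con <- talinR7R8Construct(clamped = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeConstructFile(con, path)
  back <- readConstructFile(path)
  expect_equal(handleContour(back), handleContour(con))
  expect_equal(length(domains(back)), length(domains(con)))
  for (i in seq_along(domains(con))) {
    a <- domains(con)[[i]]; b <- domains(back)[[i]]
    for (sl in c("name", "nResidues", "deltaLc", "k0", "dx", "foldedSize",
                 "clamped", "clampSpan"))
      expect_equal(slot(b, sl), slot(a, sl))
  }
  expect_error(readConstructFile(withr::local_tempfile(lines = "junk")),
               "not a")
})
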