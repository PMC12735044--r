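test_that("the packaged antioxidant panel matches its printed values", {
  m <- table1Fixture()
  expect_s4_class(m, "IndicatorMatrix")
  expect_equal(dim(indicatorValues(m)), c(7L, 6L))
  v <- indicatorValues(m)
  expect_equal(v["Lac. lactis W3C", "FICC"], 54.70)
  expect_equal(v["S. lutetiensis W3B", "OH"], 95.26)
  expect_equal(v["Leu. mesenteroides W3E", "DPPH"], 37.72)
  s <- indicatorSds(m)
  expect_equal(s["Lac. lactis W3C", "FICC"], 1.24)
  expect_true(all(indicatorOrientation(m) == "benefit"))
})

test_that("matrix assembly from tidy records is order-deterministic", {
  rec <- expand.grid(strain = c("B", "A", "C"), indicator = c("y", "x"),
                     replicate = 1:3, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  set.seed(5)
  rec$value <- runif(nrow(rec), 1, 10)
  m <- buildIndicatorMatrix(rec)
  # row order = input strain order, column order = declared indicator order
  expect_equal(strainNames(m), c("B", "A", "C"))
  expect_equal(indicatorNames(m), c("y", "x"))
  # cell = replicate mean, SD carried alongside
  b_y <- rec$value[rec$strain == "B" & rec$indicator == "y"]
  expect_equal(indicatorValues(m)["B", "y"], mean(b_y), tolerance = 1e-12)
  expect_equal(indicatorSds(m)["B", "y"], sd(b_y), tolerance = 1e-12)

  # permutation safety: shuffling rows changes nothing when orders are declared
  set.seed(9)
  for (k in 1:10) {
    shuf <- rec[sample(nrow(rec)), ]
    m2 <- buildIndicatorMatrix(shuf, indicators = c("y", "x"),
                               strains = c("B", "A", "C"))
    expect_identical(indicatorValues(m2), indicatorValues(m))
  }
})

test_that("matrix assembly fails loudly on bad cells", {
  expect_error(buildIndicatorMatrix(data.frame()),
               class = "strainscreen_validation_error")
  rec <- data.frame(strain = c("A", "A", "B"), indicator = "x",
                    value = c(1, 2, 3))
  expect_error(buildIndicatorMatrix(rec), "duplicate",
               class = "strainscreen_validation_error")
  rec2 <- data.frame(strain = c("A", "B"), indicator = c("x", "y"),
                     value = c(1, 2))
  err <- tryCatch(buildIndicatorMatrix(rec2), error = identity)
  expect_s3_class(err, "strainscreen_validation_error")
  expect_match(conditionMessage(err), "\\(A, y\\)")
  # a single strain builds but cannot be ranked
  one <- buildIndicatorMatrix(data.frame(strain = "A",
                                         indicator = c("x", "y"),
                                         value = c(1, 2)))
  expect_error(entropyWeights(one), class = "strainscreen_validation_error")
})

test_that("column summaries are exact extrema", {
  m <- table1Fixture()
  expect_equal(columnSummary(m, "ABTS", "min"), 95.86)
  expect_equal(columnSummary(m, "FRAP", "max"), 273.14)
  expect_equal(columnSummary(m, "FICC", "range"), 54.70 - 23.98)
  for (ind in indicatorNames(m)) {
    expect_lte(columnSummary(m, ind, "min"), columnSummary(m, ind, "max"))
    expect_equal(columnSummary(m, ind, "range"),
                 columnSummary(m, ind, "max") - columnSummary(m, ind, "min"))
  }
  expect_error(columnSummary(m, "nope", "min"),
               class = "strainscreen_validation_error")
  single <- IndicatorMatrix(matrix(5, 1, 1, dimnames = list("A", "x")))
  expect_equal(columnSummary(single, "x", "range"), 0)
})

test_that("positivity shift only touches offending columns", {
  v <- cbind(pos = c(2, 3, 4), mixed = c(-1, 0, 1))
  rownames(v) <- c("a", "b", "c")
  m <- IndicatorMatrix(v)
  shifted <- indicatorValues(shiftPositive(m, 0.01))
  expect_identical(shifted[, "pos"], v[, "pos"])          # bit-identical
  expect_equal(unname(shifted[, "mixed"]), c(0.01, 1.01, 2.01))
  # all-positive input is a no-op
  allpos <- IndicatorMatrix(v[, "pos", drop = FALSE])
  expect_identical(indicatorValues(shiftPositive(allpos, 0.01)),
                   indicatorValues(allpos))
  # epsilon 0 leaves a zero behind and flags the matrix entropy-unsafe
  zr <- IndicatorMatrix(cbind(x = c(0, 1, 2)))
  expect_warning(unsafe <- shiftPositive(zr, 0), "unsafe")
  expect_equal(min(indicatorValues(unsafe)), 0)
  expect_true(S4Vectors::metadata(unsafe)$entropyUnsafe)
})

test_that("the matrix CSV dialect round-trips values, SDs and labels", {
  m <- table1Fixture()
  path <- tempfile(fileext = ".csv")
  writeIndicatorMatrix(m, path)
  back <- readIndicatorMatrix(path)
  expect_equal(indicatorValues(back), indicatorValues(m))
  expect_equal(indicatorSds(back), indicatorSds(m))
  expect_equal(strainNames(back), strainNames(m))
})
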