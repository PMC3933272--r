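test_that("loading round-trips a clean matrix and cleans symbols", {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 3, 4)
  path <- writeExprFixture(m, c("A", "B", "C"))
  x <- loadExpression(path)
  expect_identical(dim(exprValues(x)), c(3L, 4L))
  expect_identical(rownames(x), c("A", "B", "C"))
  expect_equal(unname(exprValues(x)), m)

  # duplicate symbols are averaged into one row
  path2 <- writeExprFixture(rbind(rep(1, 4), rep(3, 4)), c("A", "A"))
  x2 <- loadExpression(path2)
  expect_identical(nrow(x2), 1L)
  expect_equal(unname(exprValues(x2)[1, ]), rep(2, 4))

  # rows with a blank symbol are excluded
  path3 <- writeExprFixture(rbind(1:4, 5:8), c("A", ""))
  x3 <- loadExpression(path3)
  expect_identical(rownames(x3), "A")

  # malformed numeric cells are reported, empty files rejected
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "A\t1\toops"), bad)
  expect_error(loadExpression(bad), "malformed numeric cell")
  empty <- tempfile(fileext = ".tsv")
  writeLines("gene_id\ts1\ts2", empty)
  expect_error(loadExpression(empty), "no data rows")
})

test_that("group averaging means member columns in first-appearance order", {
  m <- matrix(c(1, 3, 5), 1, 3, dimnames = list("A", c("s1", "s2", "s3")))
  x <- MirExpression(m, groupLabels = c(s1 = "gA", s2 = "gA", s3 = "gB"))
  av <- averageGroups(x)
  expect_identical(colnames(av), c("gA", "gB"))
  expect_equal(unname(exprValues(av)["A", ]), c(2, 5))

  # degenerate: all samples in one group -> single column of row means
  x1 <- MirExpression(m, groupLabels = setNames(rep("g", 3), colnames(m)))
  expect_equal(unname(exprValues(averageGroups(x1))[, 1]), 3)

  # brute-force oracle on a random 6-gene x 10-sample matrix, 4 groups
  set.seed(42)
  mm <- matrix(rnorm(60), 6, 10,
               dimnames = list(paste0("G", 1:6), paste0("s", 1:10)))
  grp <- setNames(sample(paste0("g", 1:4), 10, replace = TRUE), colnames(mm))
  av2 <- exprValues(averageGroups(MirExpression(mm, groupLabels = grp)))
  for (g in unique(grp))
    expect_equal(unname(av2[, g]),
                 unname(rowMeans(mm[, grp == g, drop = FALSE])))

  # unlabeled sample is an error naming it
  expect_error(
    averageGroups(MirExpression(mm, groupLabels = replace(grp, 2, ""))),
    "s2")
})

test_that("outlier clipping applies quantile fences and is idempotent", {
  row <- c(1, 2, 3, 4, 100)
  x <- MirExpression(matrix(row, 1, dimnames = list("A", paste0("s", 1:5))))
  clipped <- exprValues(clipOutliers(x))[1, ]
  q1 <- linPercentile(row, 0.25); q3 <- linPercentile(row, 0.75)
  expect_equal(unname(clipped), c(1, 2, 3, 4, q3 + 1.5 * (q3 - q1)))

  # constant row: fences collapse, values unchanged
  xc <- MirExpression(matrix(5, 1, 4,
                             dimnames = list("A", paste0("s", 1:4))))
  expect_equal(unname(exprValues(clipOutliers(xc))[1, ]), rep(5, 4))

  # idempotence and within-fence order preservation on 100 random rows
  set.seed(7)
  mm <- matrix(rnorm(100 * 12, sd = 3), 100, 12,
               dimnames = list(sprintf("G%03d", 1:100), paste0("s", 1:12)))
  x1 <- clipOutliers(MirExpression(mm))
  x2 <- clipOutliers(x1)
  expect_equal(exprValues(x2), exprValues(x1))
  # clipping is monotone: sorting by the original order never decreases
  for (i in seq_len(100))
    expect_true(all(diff(exprValues(x1)[i, order(mm[i, ])]) >= 0))

  # literal-quartile mode makes the upper fence unreachable
  lit <- exprValues(clipOutliers(x, literalQuartiles = TRUE))[1, ]
  expect_equal(unname(lit[5]), 100)
})

test_that("log transform is exact, guarded, and applied at most once", {
  m <- matrix(c(8, 1), 1, 2, dimnames = list("A", c("s1", "s2")))
  x <- logTransform(MirExpression(m))
  expect_equal(unname(exprValues(x)[1, ]), c(3, 0))
  expect_true(isLogTransformed(x))
  expect_error(logTransform(x), "already")

  x0 <- MirExpression(matrix(c(0, 2), 1, 2,
                             dimnames = list("A", c("s1", "s2"))))
  expect_equal(unname(exprValues(logTransform(x0, offset = 1))[1, ]),
               c(0, log2(3)))
  expect_error(logTransform(x0), "non-positive value .* 'A'")

  # round trip recovers the input
  set.seed(3)
  mm <- matrix(rexp(40) + 0.1, 4, 10,
               dimnames = list(paste0("G", 1:4), paste0("s", 1:10)))
  back <- 2^exprValues(logTransform(MirExpression(mm)))
  expect_equal(back, mm, tolerance = 1e-12)
})

test_that("centering removes row means exactly", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), paste0("s", 1:3)))
  cen <- centerRows(MirExpression(m))
  expect_equal(unname(cen$delta["A", ]), c(-1, 0, 1))
  expect_equal(unname(cen$delta["B", ]), c(0, 0, 0))
  expect_equal(unname(cen$rowMean), c(2, 5))

  set.seed(11)
  mm <- matrix(rnorm(1000 * 8, sd = 10), 1000, 8,
               dimnames = list(sprintf("G%04d", 1:1000), paste0("s", 1:8)))
  cen2 <- centerRows(MirExpression(mm))
  expect_lt(max(abs(rowSums(cen2$delta))), 1e-9 * 8 * 10)
})

test_that("gene variation is the unbiased variance and shift-invariant", {
  m <- matrix(c(1, 2, 3, 4, 4, 4), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), paste0("s", 1:3)))
  gv <- geneVariation(MirExpression(m))
  expect_equal(gv$variance, c(1, 0))

  shifted <- geneVariation(MirExpression(m + 10))
  expect_equal(shifted$variance, gv$variance)

  # centering leaves the index unchanged too
  cen <- centerRows(MirExpression(m))$delta
  expect_equal(geneVariation(MirExpression(cen))$variance, gv$variance)

  expect_error(
    geneVariation(MirExpression(matrix(1, 2, 1,
      dimnames = list(c("A", "B"), "s1")))),
    "at least two samples")
})

test_that("variance filter keeps genes at or above the threshold", {
  m <- rbind(A = c(1, 1, 1), B = c(1, 1, 2.1), C = c(0, 2, 4))
  colnames(m) <- paste0("s", 1:3)
  x <- MirExpression(m)
  expect_identical(nrow(varianceFilter(x, 0)), 3L)
  kept <- varianceFilter(x, 0.4)
  expect_identical(rownames(kept), c("B", "C"))
  expect_identical(metadata(kept)$varianceFilter$dropped, "A")
  expect_warning(varianceFilter(x, 100), "every gene")
})

test_that("the preprocessing pipeline is deterministic and ordered", {
  set.seed(5)
  mm <- matrix(rexp(8 * 6, rate = 1 / 300), 8, 6,
               dimnames = list(sprintf("G%02d", 1:8), paste0("s", 1:6)))
  grp <- setNames(rep(c("gA", "gB", "gC"), each = 2), colnames(mm))
  x <- MirExpression(mm, groupLabels = grp)
  p1 <- preprocessExpression(x)
  p2 <- preprocessExpression(MirExpression(mm, groupLabels = grp))
  expect_identical(exprValues(p1), exprValues(p2))

  # averaging happens on the linear scale, before the log transform
  manual <- logTransform(clipOutliers(averageGroups(x)))
  expect_equal(exprValues(p1), exprValues(manual))
  expect_false(
    isTRUE(all.equal(exprValues(p1),
                     exprValues(averageGroups(clipOutliers(
                       logTransform(x)))))))
})
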