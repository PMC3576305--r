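test_that("aggregation reproduces hand-computed group means and counts", {
  ce <- toyExperiment()
  gc <- aggregateCopyNumber(ce)
  y <- groupMeans(gc); n <- cellCounts(gc)
  # cnvA: g1 = (2+1+0)/3, g2 = (2+2)/2 with one missing
  expect_equal(y["cnvA", ], c(g1 = 1, g2 = 2))
  expect_equal(n["cnvA", ], c(g1 = 3L, g2 = 2L))
  # cnvB: g1 = (0+0+3)/3, g2 = 1/1
  expect_equal(y["cnvB", ], c(g1 = 1, g2 = 1))
  expect_equal(n["cnvB", ], c(g1 = 3L, g2 = 1L))
})

test_that("aggregation of constant groups is the identity on the means", {
  copies <- rbind(locusA = rep(c(2L, 0L), each = 4),
                  locusB = rep(c(1L, 2L), each = 4))
  gc <- aggregateCopyNumber(CNVExperiment(copies, group = rep(1:2, each = 4)))
  expect_equal(unname(groupMeans(gc)), rbind(c(2, 0), c(1, 2)))
})

test_that("per-locus group counts add up to the non-missing individuals", {
  set.seed(4)
  copies <- matrix(sample(c(0:4, NA), 120, replace = TRUE), nrow = 10)
  rownames(copies) <- paste0("l", 1:10)
  ce <- CNVExperiment(copies, group = sample(3, 12, replace = TRUE))
  gc <- aggregateCopyNumber(ce)
  expect_equal(unname(rowSums(cellCounts(gc))),
               unname(rowSums(!is.na(copies))))
})

test_that("empty (locus, group) cells are flagged with a warning and NA mean", {
  copies <- rbind(l1 = c(2L, 2L, NA, NA), l2 = c(1L, 1L, 2L, 2L))
  ce <- CNVExperiment(copies, group = rep(1:2, each = 2))
  expect_warning(gc <- aggregateCopyNumber(ce), "empty")
  expect_true(is.na(groupMeans(gc)["l1", "2"]))
  expect_identical(cellCounts(gc)["l1", "2"], 0L)
})

test_that("bonferroni level is exact and behaves monotonically", {
  # 8587-locus screen: the corrected level prints as 99.9994%
  expect_equal(bonferroniLevel(8587), 1 - 0.05 / 8587)
  expect_identical(sprintf("%.4f", 100 * bonferroniLevel(8587)), "99.9994")
  expect_equal(bonferroniLevel(1), 0.95)
  expect_equal(bonferroniLevel(120), 1 - 0.05 / 120)  # 0.9995833..., not 99.98%
  # strictly decreasing in alpha, strictly increasing in the locus count
  alphas <- c(0.01, 0.05, 0.1, 0.5)
  expect_true(all(diff(vapply(alphas, function(a)
    bonferroniLevel(100, a), numeric(1))) < 0))
  ns <- c(1, 10, 120, 8587)
  expect_true(all(diff(vapply(ns, bonferroniLevel, numeric(1))) > 0))
  expect_error(bonferroniLevel(0), "positive integer")
  expect_error(bonferroniLevel(10, 1.2), "alpha")
})

test_that("copy-number tables round-trip bit-exactly through disk", {
  ce <- toyExperiment()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeCopyNumberTable(ce, tmp)
  back <- readCopyNumberTable(tmp)
  expect_identical(copyNumbers(back), copyNumbers(ce))
  expect_identical(as.character(groupLabels(back)),
                   as.character(groupLabels(ce)))
  # csv + covariate variant
  ce2 <- CNVExperiment(copyNumbers(ce), group = groupLabels(ce),
                       covariate = rep(c("a", "b", "a"), 2))
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeCopyNumberTable(ce2, tmp2, missingToken = ".")
  back2 <- readCopyNumberTable(tmp2, missingToken = ".",
                               covariateCol = "covariate")
  expect_identical(copyNumbers(back2), copyNumbers(ce2))
  expect_identical(as.character(covariateLabels(back2)),
                   as.character(covariateLabels(ce2)))
})

test_that("readers reject out-of-range values and duplicate locus ids loudly", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tgroup\tcnvA\tcnvB",
               "i1\tg1\t2\t7",
               "i2\tg2\t1\t0"), tmp)
  expect_error(readCopyNumberTable(tmp), "'7'.*cnvB")
  writeLines(c("id\tgroup\tcnvA\tcnvA",
               "i1\tg1\t2\t1",
               "i2\tg2\t1\t0"), tmp)
  expect_error(readCopyNumberTable(tmp), "duplicate")
  writeLines(c("id\tgroup\tcnvA\tcnvB",
               "i1\tg1\t2\tNA",
               "i2\tg2\t1\t0"), tmp)
  back <- readCopyNumberTable(tmp)
  expect_true(is.na(copyNumbers(back)["cnvB", "i1"]))
})

test_that("CNVExperiment enforces its invariants", {
  expect_error(CNVExperiment(matrix(7L, 1, 2), group = 1:2), "0, 6")
  expect_error(CNVExperiment(matrix(2L, 1, 2), group = c(1, 1)),
               "at least 2 groups")
  m <- matrix(2L, 2, 2, dimnames = list(c("a", "a"), NULL))
  expect_error(CNVExperiment(m, group = 1:2), "unique")
  # group levels keep first-appearance order
  ce <- CNVExperiment(matrix(0:3, 1, 4), group = c("z", "b", "z", "a"))
  expect_identical(levels(groupLabels(ce)), c("z", "b", "a"))
})
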