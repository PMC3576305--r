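test_that("chi-square statistic matches hand computation and stats::chisq.test", {
  # perfect independence
  r0 <- chisqTestTable(matrix(10, 2, 2))
  expect_equal(r0$statistic, 0); expect_equal(r0$p.value, 1)
  # all expected counts 15: X2 = 4 * 25/15
  r1 <- chisqTestTable(matrix(c(10, 20, 20, 10), 2))
  expect_equal(r1$statistic, 100 / 15)
  expect_identical(r1$df, 1L)
  # random tables against the reference implementation and a brute-force sum
  set.seed(21)
  for (i in 1:10) {
    tab <- matrix(rpois(9, 12) + 1, 3, 3)
    ours <- chisqTestTable(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$statistic, oracleChisq(tab), tolerance = 1e-10)
  }
  # degenerate after dropping an empty column
  dg <- chisqTestTable(cbind(c(5, 3), c(0, 0)))
  expect_true(dg$degenerate); expect_equal(dg$p.value, 1)
  # empty categories do not change the statistic
  tab <- matrix(c(10, 20, 20, 10), 2)
  expect_equal(chisqTestTable(rbind(tab, c(0, 0)))$statistic,
               chisqTestTable(tab)$statistic)
})

test_that("Kruskal-Wallis matches the textbook value and stats::kruskal.test", {
  # untied case: groups {1,2,3} vs {4,5,6} give H = 27/7
  r <- kruskalWallisTest(1:6, rep(1:2, each = 3))
  expect_equal(r$statistic, 27 / 7, tolerance = 1e-12)
  # identical values: H = 0, p = 1
  r0 <- kruskalWallisTest(rep(2, 9), rep(1:3, 3))
  expect_equal(r0$statistic, 0); expect_equal(r0$p.value, 1)
  # heavily tied copy data against the reference implementation
  set.seed(22)
  for (i in 1:8) {
    x <- sample(0:2, 300, replace = TRUE, prob = c(0.05, 0.2, 0.75))
    g <- sample(3, 300, replace = TRUE)
    ours <- kruskalWallisTest(x, g)
    ref <- stats::kruskal.test(x, g)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
  # the counts interface agrees with the raw-data interface
  x <- c(0, 0, 1, 2, 2, 2, 1, 2); g <- c(1, 2, 1, 2, 1, 2, 2, 1)
  expect_equal(kruskalWallisTest(x, g)$statistic,
               kruskalWallisTest(counts = table(x, g))$statistic)
})

test_that("multinomial LRT maximises the likelihood and nulls out correctly", {
  # intercept-only maximum has the closed form sum n_p log(n_p / n)
  set.seed(23)
  x <- sample(0:2, 60, replace = TRUE)
  g <- sample(3, 60, replace = TRUE)
  r <- multinomLRTest(x, g)
  np <- table(g)
  expect_equal(r$logLikNull, sum(np * log(np / 60)), tolerance = 1e-12)
  expect_true(r$p.value >= 0 && r$p.value <= 1)
  expect_identical(r$df, 2L)

  # 12-individual example: maximised log-likelihood matches a brute-force
  # optimiser over the same multinomial likelihood
  x12 <- c(0, 1, 2, 2, 1, 0, 2, 2, 1, 2, 0, 1)
  g12 <- rep(1:3, each = 4)
  r12 <- multinomLRTest(x12, g12)
  bruteLL <- function(par) {   # par = (a2, b2, a3, b3), group 1 baseline
    eta <- cbind(0, par[1] + par[2] * x12, par[3] + par[4] * x12)
    sum(eta[cbind(seq_along(g12), g12)] - log(rowSums(exp(eta))))
  }
  opt <- optim(rep(0, 4), function(p) -bruteLL(p), method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(r12$logLik, -opt$value, tolerance = 1e-6)

  # agreement with nnet::multinom deviance on a larger sample
  skip_if_not_installed("nnet")
  fit <- nnet::multinom(factor(g) ~ x, trace = FALSE, reltol = 1e-12)
  expect_equal(multinomLRTest(x, g)$logLik, -fit$deviance / 2, tolerance = 1e-5)
})

test_that("multinomial LR statistic is invariant to affine predictor rescaling", {
  set.seed(24)
  x <- sample(0:4, 150, replace = TRUE)
  g <- sample(2, 150, replace = TRUE, prob = c(0.4, 0.6))
  a <- multinomLRTest(x, g)$statistic
  b <- multinomLRTest(3 * x - 7, g)$statistic
  expect_equal(a, b, tolerance = 1e-7)
})

test_that("categorical coding changes the degrees of freedom accordingly", {
  set.seed(25)
  x <- sample(0:2, 200, replace = TRUE)
  g <- sample(3, 200, replace = TRUE)
  rn <- multinomLRTest(x, g, coding = "numeric")
  rc <- multinomLRTest(x, g, coding = "categorical")
  expect_identical(rn$df, 2L)
  expect_identical(rc$df, 4L)
  expect_gte(rc$statistic, rn$statistic - 1e-8)  # nested models
})

test_that("per-locus type-I error is near nominal under the null", {
  sp <- scenarioSpec(nLoci = 2000, nPerGroup = 500, oddsRatio = 1, seed = 31)
  sim <- simulateCNVDataset(sp, repSeed = 77)
  se3 <- 3 * sqrt(0.05 * 0.95 / 2000)
  for (m in c("chisq", "kruskal", "multinom")) {
    p <- baselinePValues(sim$experiment, method = m)
    expect_lt(abs(mean(p < 0.05) - 0.05), se3)
  }
})

test_that("baseline p-values are invariant to group relabeling", {
  sp <- scenarioSpec(nLoci = 30, nPerGroup = 80, oddsRatio = 2, seed = 41)
  sim <- simulateCNVDataset(sp, repSeed = 5)
  ce <- sim$experiment
  perm <- c(group2 = "b", group1 = "c", group3 = "a")
  ce2 <- CNVExperiment(copyNumbers(ce),
                       group = perm[as.character(groupLabels(ce))])
  for (m in c("chisq", "kruskal"))
    expect_equal(unname(baselinePValues(ce, m)),
                 unname(baselinePValues(ce2, m)), tolerance = 1e-12)
})
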