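test_that("quantile criterion flags intervals that exclude zero", {
  set.seed(1)
  # all draws well above zero -> gain at any reasonable level
  d <- decideQuantile(runif(5000, 0.4, 0.6), level = 0.99)
  expect_true(d$significant); expect_identical(d$direction, "gain")
  # symmetric draws -> not significant
  d0 <- decideQuantile(rnorm(5000), level = 0.95)
  expect_false(d0$significant); expect_identical(d0$direction, "none")
  # Normal(0.5, 0.1) at the 99.98% level: closed-form interval ~ [0.13, 0.87]
  z <- qnorm(1 - 2e-4 / 2)
  dn <- suppressWarnings(decideQuantile(rnorm(1e4, 0.5, 0.1), level = 0.9998))
  expect_true(dn$significant)
  expect_equal(dn$lower, 0.5 - z * 0.1, tolerance = 0.05)
  expect_equal(dn$upper, 0.5 + z * 0.1, tolerance = 0.05)
  # too few draws for the tail -> warning recommending the normal rule
  expect_warning(decideQuantile(rnorm(100), level = 0.999), "normal-approximation")
})

test_that("normal-approximation criterion matches the standard normal quantile", {
  expect_false(decideNormal(0, 3, 0.9998)$significant)
  # required z at 99.98% is 3.719; mean 5 sd 1 crosses it, mean 3 does not
  expect_true(decideNormal(5, 1, 0.9998)$significant)
  expect_false(decideNormal(3, 1, 0.9998)$significant)
  expect_equal(decideNormal(5, 1, 0.9998)$lower, 5 - qnorm(0.9999), tolerance = 1e-12)
  # degenerate sd: significant iff mean non-zero
  expect_true(decideNormal(0.2, 0, 0.99)$significant)
  expect_false(decideNormal(0, 0, 0.99)$significant)
  expect_identical(decideNormal(-4, 1, 0.99)$direction, "loss")
})

test_that("posterior-probability criterion uses the two-sided Bonferroni tail", {
  expect_true(decidePosteriorProb(runif(100, 0.1, 1), alpha = 0.05,
                                  nLoci = 10)$significant)     # q = 0
  half <- c(rep(-1, 50), rep(1, 50))
  d <- decidePosteriorProb(half, alpha = 0.05, nLoci = 10)
  expect_equal(d$tailProb, 0.5); expect_false(d$significant)
  # Normal(0.5, 0.1): q ~ Phi(-5) = 2.9e-7 < 0.05/(2*500) = 5e-5
  set.seed(2)
  dn <- decidePosteriorProb(rnorm(2e4, 0.5, 0.1), alpha = 0.05, nLoci = 500)
  expect_true(dn$significant)
})

test_that("raising the credible level never creates new significant calls", {
  set.seed(3)
  draws <- matrix(rnorm(2000 * 30, rep(seq(-0.5, 0.5, length.out = 30),
                                       each = 2000), 0.2), 2000, 30)
  levels <- c(0.8, 0.95, 0.99, 0.999)
  sigs <- lapply(levels, function(l) suppressWarnings(decideQuantile(draws, l))$significant)
  for (i in seq_len(length(levels) - 1))
    expect_true(all(sigs[[i + 1]] <= sigs[[i]]))
  sigsN <- lapply(levels, function(l) decideNormal(colMeans(draws),
                                                   apply(draws, 2, sd), l)$significant)
  for (i in seq_len(length(levels) - 1))
    expect_true(all(sigsN[[i + 1]] <= sigsN[[i]]))
})

test_that("quantile and normal criteria agree on exactly-normal draws", {
  set.seed(4)
  mu <- runif(50, -1, 1); s <- runif(50, 0.05, 0.5)
  draws <- matrix(rnorm(1e5 * 50, rep(mu, each = 1e5), rep(s, each = 1e5)),
                  1e5, 50)
  dq <- suppressWarnings(decideQuantile(draws, 0.999))
  dn <- decideNormal(colMeans(draws), apply(draws, 2, sd), 0.999)
  expect_gte(mean(dq$significant == dn$significant), 0.99)
})

test_that("confusion rates count detections per locus", {
  # perfect and empty detectors
  truth <- setNames(c(TRUE, TRUE, rep(FALSE, 498)), paste0("l", 1:500))
  expect_equal(confusionRates(truth, truth), c(TPR = 100, TNR = 100))
  none <- setNames(rep(FALSE, 500), names(truth))
  expect_equal(confusionRates(none, truth), c(TPR = 0, TNR = 100))
  # 1 true positive + 1 false positive out of 2 associated / 498 null
  det <- none; det["l1"] <- TRUE; det["l9"] <- TRUE
  expect_equal(confusionRates(det, truth),
               c(TPR = 50, TNR = 100 * 497 / 498))
  # permutation invariance in locus order
  perm <- sample(names(truth))
  expect_equal(confusionRates(det[perm], truth), confusionRates(det, truth))
  # no associated loci -> TPR undefined
  expect_true(is.na(confusionRates(none, setNames(rep(FALSE, 500),
                                                  names(truth)))["TPR"]))
})
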