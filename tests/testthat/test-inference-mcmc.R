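test_that("Gibbs full conditionals match grid-normalised brute force", {
  y <- matrix(c(2.1, 1.9, 2.0, 2.2), 2, 2,
              dimnames = list(c("l1", "l2"), c("gA", "gB")))
  gc <- GroupedCounts(y)
  cfg <- scmConfig(iterations = 10, burnIn = 1, thin = 1)
  dat <- sharedCNV:::.scmData(gc, cfg)
  state <- list(alpha = c(2, 2.05), beta = c(0.8, 1.1), theta = c(0.3, -0.2),
                lambda = matrix(c(0.05, -0.1, 0.02, 0), 2, 2),
                nu = c(0.15, 0.2), sigma = c(0.1, 0.12),
                w = matrix(c(1.3, 0.7, 1, 2), 2, 2),
                gamma = 0, xi = matrix(0, 2, 1), wxi = matrix(1, 2, 1),
                sigmaXi = 1, omega = NULL, hasShared = TRUE, hasSpecific = TRUE)
  jp <- function(st) oracleLogPost(y, st$alpha, st$beta, st$theta, st$lambda,
                                   st$nu, st$sigma, st$w)
  checkCond <- function(mom, set1, center, sd0) {
    grid <- seq(center - 8 * sd0, center + 8 * sd0, length.out = 4001)
    lp <- vapply(grid, function(v) jp(set1(state, v)), numeric(1))
    o <- gridMoments(grid, lp)
    expect_equal(mom$mean, o$mean, tolerance = 1e-5)
    expect_equal(mom$sd, o$sd, tolerance = 1e-4)
  }
  mA <- sharedCNV:::.condAlpha(state, dat, cfg)
  checkCond(list(mean = mA$mean[1], sd = mA$sd[1]),
            function(st, v) { st$alpha[1] <- v; st }, mA$mean[1], mA$sd[1])
  mT <- sharedCNV:::.condTheta(state, dat, cfg)
  checkCond(list(mean = mT$mean[2], sd = mT$sd[2]),
            function(st, v) { st$theta[2] <- v; st }, mT$mean[2], mT$sd[2])
  mL <- sharedCNV:::.condLambda(state, dat, cfg)
  checkCond(list(mean = mL$mean[1, 1], sd = mL$sd[1, 1]),
            function(st, v) { st$lambda[1, 1] <- v; st }, mL$mean[1, 1], mL$sd[1, 1])
  mB <- sharedCNV:::.condBeta(state, dat, cfg)
  checkCond(list(mean = mB$mean[2], sd = mB$sd[2]),
            function(st, v) { st$beta[2] <- v; st }, mB$mean[2], mB$sd[2])
})

test_that("single-cell posterior of alpha matches the conjugate closed form", {
  gc <- GroupedCounts(matrix(2.3, 1, 1))
  oracle <- conjugatePosterior(2.3, nu = 0.2)
  cfg <- scmConfig(chains = 2, iterations = 3000, burnIn = 500, thin = 1,
                   fixNu = 0.2, seed = 6)
  fit <- suppressWarnings(fitMCMC(gc, cfg, components = character(0)))
  a <- as.vector(fit@samples$alpha)
  expect_equal(mean(a), oracle$mean, tolerance = 3 * oracle$sd / sqrt(1000))
  expect_equal(sd(a), oracle$sd, tolerance = 0.1 * oracle$sd)
})

test_that("t4 scale mixture has the right variance and distribution", {
  set.seed(31)
  x <- rT4(1e5, sigma = 0.7)
  # var of a t with 4 df and scale 0.7 is 2 * 0.49
  expect_equal(var(x), 2 * 0.49, tolerance = 0.1 * 2 * 0.49)
  ks <- suppressWarnings(stats::ks.test(x, function(q) stats::pt(q / 0.7, df = 4)))
  expect_gt(ks$p.value, 0.01)
})

test_that("MCMC runs are bit-reproducible and respect the sign constraint", {
  lam <- matrix(0, 15, 3); lam[3, 2] <- 0.4
  gc <- simulateFromModel(2, 0.4, lam, nu = 0.1, seed = 8)
  cfg <- scmConfig(chains = 2, iterations = 400, burnIn = 100, thin = 3, seed = 11)
  f1 <- suppressWarnings(fitMCMC(gc, cfg))
  f2 <- suppressWarnings(fitMCMC(gc, cfg))
  expect_identical(f1@samples, f2@samples)
  expect_identical(dim(f1@samples$alpha), c(100L, 2L, 3L))
  # symmetric formulation: each kept draw satisfies sum(beta) >= 0
  bsum <- apply(f1@samples$beta, c(1, 2), sum)
  expect_true(all(bsum >= 0))
})

test_that("posterior is invariant to relabeling groups with their data", {
  lam <- matrix(0, 40, 3); lam[5, 1] <- 0.3
  gc <- simulateFromModel(c(1.9, 2, 2.1), 0.3, lam, nu = 0.08, seed = 12)
  cfg <- scmConfig(chains = 2, iterations = 2000, burnIn = 500, thin = 2, seed = 4)
  f <- suppressWarnings(fitMCMC(gc, cfg))
  perm <- c(3, 1, 2)
  y2 <- groupMeans(gc)[, perm]
  colnames(y2) <- paste0("group", 1:3)
  f2 <- suppressWarnings(fitMCMC(GroupedCounts(y2), cfg))
  expect_equal(f2@summaries$alpha$mean, f@summaries$alpha$mean[perm],
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("null data give near-total credible-interval coverage of zero", {
  sp <- scenarioSpec(nLoci = 40, nPerGroup = 400, oddsRatio = 1, seed = 14)
  sim <- simulateCNVDataset(sp, repSeed = 3)
  gc <- aggregateCopyNumber(sim$experiment)
  cfg <- scmConfig(chains = 2, iterations = 1500, burnIn = 300, thin = 2, seed = 2)
  fit <- suppressWarnings(fitMCMC(gc, cfg))
  dec <- suppressWarnings(callSpecific(fit, criterion = "quantile", level = 0.95))
  expect_gte(mean(!dec$significant), 0.99)
})

test_that("intercepts recover the true mean copy number of two", {
  sp <- scenarioSpec(nLoci = 60, nPerGroup = 400, oddsRatio = 1.5, seed = 15)
  sim <- simulateCNVDataset(sp, repSeed = 9)
  gc <- aggregateCopyNumber(sim$experiment)
  cfg <- scmConfig(chains = 2, iterations = 1500, burnIn = 300, thin = 2, seed = 2)
  fit <- suppressWarnings(fitMCMC(gc, cfg))
  # simulated deletion frequencies are U(0.01, 0.1): E[copies] = 2(1 - E q)
  expect_true(all(abs(fit@summaries$alpha$mean - 1.9) < 0.1))
})

test_that("asymmetric formulation pins the reference loading at one", {
  lam <- matrix(0, 20, 3)
  gc <- simulateFromModel(2, c(1, 0.8, 1.2), lam, nu = 0.1, seed = 16)
  cfg <- scmConfig(formulation = "asymmetric", referenceGroup = 1,
                   chains = 2, iterations = 600, burnIn = 100, thin = 2, seed = 5)
  fit <- suppressWarnings(fitMCMC(gc, cfg))
  expect_true(all(fit@samples$beta[, , 1] == 1))
  expect_false(all(fit@samples$beta[, , 2] == 1))
})

test_that("covariate layer: degenerate single level reduces to the base model", {
  sp <- scenarioSpec(nLoci = 20, nPerGroup = 100, oddsRatio = 2, seed = 17)
  sim <- simulateCNVDataset(sp, repSeed = 4)
  ce <- sim$experiment
  ceCov <- CNVExperiment(copyNumbers(ce), group = groupLabels(ce),
                         covariate = rep("only", ncol(ce)))
  cfg <- scmConfig(chains = 1, iterations = 400, burnIn = 100, thin = 2, seed = 3)
  fBase <- fitMCMC(aggregateCopyNumber(ce), cfg)
  fCov <- fitMCMC(aggregateCopyNumber(ceCov, useCovariate = TRUE), cfg)
  expect_identical(fBase@samples$lambda, fCov@samples$lambda)
})

test_that("covariate effects are recovered and null when absent", {
  set.seed(18)
  J <- 25; nCell <- 150
  qs <- runif(J, 0.2, 0.4)
  mkCell <- function(qv) vapply(qv, function(q)
    simulateCommonLocus(q, nCell), integer(nCell))
  # stratum 2 has deletion frequency lowered by 0.15 -> mean copies +0.3
  copies <- rbind()
  blocks <- list(g1k1 = qs, g2k1 = qs, g1k2 = qs - 0.15, g2k2 = qs - 0.15)
  mats <- lapply(blocks, function(qv) t(mkCell(qv)))
  copies <- do.call(cbind, mats)
  rownames(copies) <- paste0("l", seq_len(J))
  group <- rep(c("g1", "g2", "g1", "g2"), each = nCell)
  strat <- rep(c("k1", "k1", "k2", "k2"), each = nCell)
  ce <- CNVExperiment(copies, group = group, covariate = strat)
  cfg <- scmConfig(chains = 2, iterations = 1500, burnIn = 300, thin = 2, seed = 7)
  fit <- suppressWarnings(fitMCMC(aggregateCopyNumber(ce), cfg))
  gdraws <- as.vector(fit@samples$gamma[, , 1])
  ci <- quantile(gdraws, c(0.025, 0.975))
  expect_true(ci[1] < 0.3 && 0.3 < ci[2])
  expect_lt(abs(mean(gdraws) - 0.3), 0.1)

  # no covariate effect -> gamma interval covers 0
  ceNull <- CNVExperiment(do.call(cbind, lapply(1:4, function(i) t(mkCell(qs)))),
                          group = group, covariate = strat)
  fit0 <- suppressWarnings(fitMCMC(aggregateCopyNumber(ceNull), cfg))
  ci0 <- quantile(as.vector(fit0@samples$gamma[, , 1]), c(0.025, 0.975))
  expect_true(ci0[1] < 0 && 0 < ci0[2])
})

test_that("pathway-level means are detected when present and null otherwise", {
  J <- 30
  lamNull <- matrix(sharedCNV::rT4(J * 2, 0.03), J, 2)
  gc0 <- simulateFromModel(2, 0.2, lamNull, nu = 0.05, seed = 19)
  pmap <- setNames(rep("pw1", J), rownames(groupMeans(gc0)))
  cfg <- scmConfig(pathwayMap = pmap, chains = 2, iterations = 1500,
                   burnIn = 300, thin = 2, seed = 8)
  f0 <- suppressWarnings(fitMCMC(gc0, cfg))
  ci0 <- quantile(as.vector(f0@samples$omega[, , 1]), c(0.025, 0.975))
  expect_true(ci0[1] < 0 && 0 < ci0[2])

  lamShift <- lamNull; lamShift[, 1] <- lamShift[, 1] + 0.4
  gc1 <- simulateFromModel(2, 0.2, lamShift, nu = 0.05, seed = 20)
  f1 <- suppressWarnings(fitMCMC(gc1, cfg))
  ci1 <- quantile(as.vector(f1@samples$omega[, , 1]), c(0.025, 0.975))
  expect_gt(ci1[1], 0)
  # unmapped loci are refused
  expect_error(fitMCMC(gc1, scmConfig(pathwayMap = pmap[-1], chains = 1,
                                      iterations = 50, burnIn = 10)),
               "unmapped")
})
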