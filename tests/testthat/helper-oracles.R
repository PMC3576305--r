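# Shared fixtures and independent oracles (kept deliberately separate from
# the package's own computational paths).

# hand-sized experiment: 2 loci x 6 individuals, 2 groups, one missing call
toyExperiment <- function() {
  copies <- matrix(c(2L, 1L, 0L, 2L, 2L, NA,
                     0L, 0L, 3L, 1L, NA, NA),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("cnvA", "cnvB"), paste0("ind", 1:6)))
  CNVExperiment(copies, group = rep(c("g1", "g2"), each = 3))
}

# joint log posterior of the shared-component model (location parameters,
# conditional on scales and mixture weights), written out long-hand
oracleLogPost <- function(y, alpha, beta, theta, lambda, nu, sigma, w) {
  ll <- 0
  for (j in seq_len(nrow(y))) for (p in seq_len(ncol(y))) {
    if (is.na(y[j, p])) next
    ll <- ll +
      dnorm(y[j, p], alpha[p] + beta[p] * theta[j] + lambda[j, p],
            nu[p], log = TRUE) +
      dnorm(lambda[j, p], 0, sigma[p] / sqrt(w[j, p]), log = TRUE)
  }
  ll + sum(dnorm(theta, 0, 1, log = TRUE)) +
    sum(dnorm(alpha, 0, sqrt(1000), log = TRUE)) +
    sum(dnorm(beta, 0, sqrt(100), log = TRUE))
}

# normalized mean/sd of a univariate density evaluated on a grid
gridMoments <- function(grid, logDens) {
  wdens <- exp(logDens - max(logDens))
  wdens <- wdens / sum(wdens)
  m <- sum(wdens * grid)
  list(mean = m, sd = sqrt(sum(wdens * (grid - m)^2)))
}

# closed-form Normal-Normal posterior for a single observation:
# y ~ N(alpha, nu^2), alpha ~ N(0, 1000)
conjugatePosterior <- function(y, nu) {
  prec <- 1 / nu^2 + 1 / 1000
  list(mean = (y / nu^2) / prec, sd = sqrt(1 / prec))
}

# brute-force Pearson chi-square on a table, independent spelling
oracleChisq <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  tot <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / tot
    stat <- stat + (tab[i, j] - e)^2 / e
  }
  stat
}
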