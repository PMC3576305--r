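# Gibbs sampler for the shared-component model
#
#   y[j,k,p] ~ N(alpha_p + gamma_k + beta_p * theta_j + lambda_jp + xi_jk, nu_p^2)
#   theta_j ~ N(0, 1)   lambda_jp ~ t4(omega_{g(j),p}, sigma_p^2)
#
# The t4 specific components are represented as a scale mixture of normals,
# lambda | w ~ N(omega, sigma^2 / w), w ~ Gamma(2, 2), which keeps every
# location-parameter update conjugate; nu_p, sigma_p (half-Normal priors)
# are updated by slice sampling on the log scale.

.scmData <- function(gc, cfg) {
  y <- gc@y; n <- gc@n
  J <- dim(y)[1]; K <- dim(y)[2]; P <- dim(y)[3]
  M <- array(as.numeric(n > 0), dim = dim(n))
  if (any(apply(M, 1, sum) == 0)) stop("a locus has no observed cell")
  if (K > 1L) {
    cellEmpty <- apply(M, c(2, 3), sum) == 0
    if (any(cellEmpty))
      stop("a (covariate level x group) cell is empty at every locus")
  }
  y0 <- y; y0[n == 0] <- 0
  if (any(!is.finite(y0))) stop("non-finite aggregated values")
  pathIdx <- NULL; pathways <- character(0)
  if (length(cfg@pathwayMap) > 0) {
    ids <- dimnames(y)[[1]]
    if (!all(ids %in% names(cfg@pathwayMap)))
      stop("pathwayMap leaves loci unmapped: ",
           paste(utils::head(setdiff(ids, names(cfg@pathwayMap)), 3), collapse = ", "))
    pw <- cfg@pathwayMap[ids]
    pathways <- unique(pw)
    pathIdx <- match(pw, pathways)
  }
  Mflat <- matrix(as.vector(M), J * K, P)
  list(y0 = y0, M = M, J = J, K = K, P = P,
       Mflat = Mflat, cntP = colSums(Mflat),
       MK = matrix(as.vector(M), J, K * P),
       loci = dimnames(y)[[1]], covLevels = dimnames(y)[[2]],
       groups = dimnames(y)[[3]], pathIdx = pathIdx, pathways = pathways)
}

# fitted-mean array with selected components left out
.muArray <- function(state, dat, exclude = character(0)) {
  J <- dat$J; K <- dat$K; P <- dat$P
  if (K == 1L) {          # fast path: plain loci x groups matrix
    mu <- if (.excl("alpha", exclude)) matrix(0, J, P)
    else matrix(rep(state$alpha, each = J), J, P)
    if (!.excl("shared", exclude) && state$hasShared)
      mu <- mu + outer(state$theta, state$beta)
    if (!.excl("specific", exclude) && state$hasSpecific)
      mu <- mu + state$lambda
    dim(mu) <- c(J, 1L, P)
    return(mu)
  }
  mu <- array(0, dim = c(J, K, P))
  if (!"alpha" %in% exclude)
    mu <- mu + array(rep(state$alpha, each = J * K), dim = c(J, K, P))
  if (!"shared" %in% exclude && state$hasShared) {
    bt <- outer(state$theta, state$beta)
    mu <- mu + array(bt[, rep(seq_len(P), each = K), drop = FALSE], dim = c(J, K, P))
  }
  if (!"specific" %in% exclude && state$hasSpecific)
    mu <- mu + array(state$lambda[, rep(seq_len(P), each = K), drop = FALSE],
                     dim = c(J, K, P))
  if (K > 1L) {
    if (!"gamma" %in% exclude)
      mu <- mu + array(rep(rep(state$gamma, each = J), times = P), dim = c(J, K, P))
    if (!"xi" %in% exclude)
      mu <- mu + array(rep(as.vector(state$xi), times = P), dim = c(J, K, P))
  }
  mu
}

.excl <- function(what, exclude) length(exclude) > 0L && what %in% exclude

.sumOverK <- function(A, J, K, P) {
  if (K == 1L) return(matrix(A, J, P))
  m <- matrix(A, J, K * P)
  vapply(seq_len(P), function(p)
    rowSums(m[, ((p - 1) * K + 1):(p * K), drop = FALSE]), numeric(J))
}

.sumOverP <- function(A, J, K, P, wp = rep(1, P)) {
  m <- matrix(A, J, K * P)
  out <- matrix(0, J, K)
  for (k in seq_len(K))
    out[, k] <- m[, k + K * (seq_len(P) - 1), drop = FALSE] %*% wp
  out
}

.omegaMatrix <- function(state, dat) {
  if (is.null(dat$pathIdx)) return(matrix(0, dat$J, dat$P))
  state$omega[dat$pathIdx, , drop = FALSE]
}

# --- full conditionals (each returns mean and sd on the sampling scale) ---

.condTheta <- function(state, dat, cfg) {
  E <- (dat$y0 - .muArray(state, dat, exclude = "shared")) * dat$M
  wv <- rep(state$beta / state$nu^2, each = dat$K)
  num <- matrix(E, dat$J, dat$K * dat$P) %*% wv
  prec <- 1 / cfg@sharedVarianceFixed +
    dat$MK %*% rep(state$beta^2 / state$nu^2, each = dat$K)
  list(mean = as.vector(num / prec), sd = as.vector(1 / sqrt(prec)))
}

.condLambda <- function(state, dat, cfg) {
  E <- (dat$y0 - .muArray(state, dat, exclude = "specific")) * dat$M
  invNu2 <- rep(1 / state$nu^2, each = dat$J)
  if (dat$K == 1L) {
    dim(E) <- c(dat$J, dat$P)
    D <- E * invNu2
    dataPrec <- dat$Mflat * invNu2
  } else {
    D <- .sumOverK(E, dat$J, dat$K, dat$P) * invNu2
    dataPrec <- .sumOverK(dat$M, dat$J, dat$K, dat$P) * invNu2
  }
  prec0 <- state$w * rep(1 / state$sigma^2, each = dat$J)
  prec <- dataPrec + prec0
  num <- if (is.null(dat$pathIdx)) D else D + prec0 * .omegaMatrix(state, dat)
  list(mean = num / prec, sd = 1 / sqrt(prec))
}

.condAlpha <- function(state, dat, cfg) {
  E <- (dat$y0 - .muArray(state, dat, exclude = "alpha")) * dat$M
  num <- colSums(matrix(E, dat$J * dat$K, dat$P)) / state$nu^2
  prec <- dat$cntP / state$nu^2 + 1 / .PRIOR$alphaVar
  list(mean = num / prec, sd = 1 / sqrt(prec))
}

.condBeta <- function(state, dat, cfg) {
  E <- (dat$y0 - .muArray(state, dat, exclude = "shared")) * dat$M
  thA <- rep(state$theta, times = dat$K * dat$P)
  num <- colSums(matrix(as.vector(E) * thA, dat$J * dat$K, dat$P)) / state$nu^2
  prec <- colSums(matrix(as.vector(dat$M) * thA^2, dat$J * dat$K, dat$P)) /
    state$nu^2 + 1 / .PRIOR$betaVar
  list(mean = num / prec, sd = 1 / sqrt(prec))
}

.condGamma <- function(state, dat, cfg) {
  E <- (dat$y0 - .muArray(state, dat, exclude = "gamma")) * dat$M
  w <- rep(1 / state$nu^2, each = dat$K)
  cs <- colSums(matrix(E, dat$J, dat$K * dat$P)) * w
  cm <- colSums(matrix(dat$M, dat$J, dat$K * dat$P)) * w
  num <- rowSums(matrix(cs, dat$K, dat$P))
  prec <- rowSums(matrix(cm, dat$K, dat$P)) + 1 / .PRIOR$gammaVar
  list(mean = num / prec, sd = 1 / sqrt(prec))
}

.condXi <- function(state, dat, cfg) {
  E <- (dat$y0 - .muArray(state, dat, exclude = "xi")) * dat$M
  num <- .sumOverP(E, dat$J, dat$K, dat$P, wp = 1 / state$nu^2)
  prec <- .sumOverP(dat$M, dat$J, dat$K, dat$P, wp = 1 / state$nu^2) +
    state$wxi / state$sigmaXi^2
  list(mean = num / prec, sd = 1 / sqrt(prec))
}

.condOmega <- function(state, dat, cfg) {
  G <- length(dat$pathways)
  wS <- state$w * rep(1 / state$sigma^2, each = nrow(state$w))
  num <- rowsum(wS * state$lambda, dat$pathIdx, reorder = FALSE)
  prec <- rowsum(wS, dat$pathIdx, reorder = FALSE) + 1 / .PRIOR$omegaVar
  list(mean = num / prec, sd = 1 / sqrt(prec))
}

# slice sampler (univariate, stepping out + shrinkage)
.sliceSample <- function(x0, logf, w = 1, maxSteps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("non-finite log density in slice sampler")
  y <- f0 - rexp(1)
  u <- runif(1)
  L <- x0 - w * u; R <- L + w
  k <- maxSteps
  while (k > 0L && logf(L) > y) { L <- L - w; k <- k - 1L }
  k <- maxSteps
  while (k > 0L && logf(R) > y) { R <- R + w; k <- k - 1L }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

.halfNormLog <- function(x, sd) dnorm(x, 0, sd, log = TRUE)  # constant factor irrelevant

.updateNu <- function(state, dat, cfg) {
  E <- (dat$y0 - .muArray(state, dat)) * dat$M
  if (cfg@equalGroupVariance) {
    SS <- sum(E^2); cnt <- sum(dat$M)
    lf <- function(t) {
      v <- exp(t)
      -cnt * t - SS / (2 * v^2) + .halfNormLog(v, .PRIOR$scaleSd) + t
    }
    state$nu <- rep(exp(.sliceSample(log(state$nu[1]), lf)), dat$P)
  } else {
    SS <- colSums(matrix(E^2, dat$J * dat$K, dat$P))
    cnt <- dat$cntP
    for (p in seq_len(dat$P)) {
      lf <- local({
        ss <- SS[p]; np <- cnt[p]
        function(t) {
          v <- exp(t)
          -np * t - ss / (2 * v^2) + .halfNormLog(v, .PRIOR$scaleSd) + t
        }
      })
      state$nu[p] <- exp(.sliceSample(log(state$nu[p]), lf))
    }
  }
  state
}

.updateSigma <- function(state, dat, cfg) {
  om <- .omegaMatrix(state, dat)
  Tp <- colSums(state$w * (state$lambda - om)^2)
  for (p in seq_len(dat$P)) {
    lf <- local({
      tp <- Tp[p]; np <- dat$J
      function(t) {
        v <- exp(t)
        -np * t - tp / (2 * v^2) + .halfNormLog(v, .PRIOR$scaleSd) + t
      }
    })
    state$sigma[p] <- exp(.sliceSample(log(state$sigma[p]), lf))
  }
  state
}

.updateSigmaXi <- function(state, dat, cfg) {
  free <- state$xi[, -1, drop = FALSE]
  Tx <- sum(state$wxi[, -1, drop = FALSE] * free^2)
  np <- length(free)
  lf <- function(t) {
    v <- exp(t)
    -np * t - Tx / (2 * v^2) + .halfNormLog(v, .PRIOR$scaleSd) + t
  }
  state$sigmaXi <- exp(.sliceSample(log(state$sigmaXi), lf))
  state
}

#' Draws from a scaled Student-t with 4 df via its normal scale mixture
#'
#' `x = z / sqrt(w)` with `z ~ N(0, sigma^2)` and `w ~ Gamma(2, 2)` is
#' marginally t-distributed with 4 degrees of freedom and scale `sigma`
#' (variance `2 sigma^2`).  This is the representation the Gibbs sampler
#' uses for the specific components.
#'
#' @param n number of draws.
#' @param sigma scale (recycled).
#' @param centre location (recycled).
#' @return numeric vector of draws.
#' @export
rT4 <- function(n, sigma = 1, centre = 0) {
  centre + rnorm(n, 0, sigma) / sqrt(rgamma(n, shape = .PRIOR$tdf / 2,
                                            rate = .PRIOR$tdf / 2))
}

.initState <- function(dat, cfg, components, jitterRng = FALSE) {
  P <- dat$P; J <- dat$J; K <- dat$K
  obs <- dat$M > 0
  gm <- sum(dat$y0[obs]) / sum(dat$M)
  colMeanP <- colSums(matrix(dat$y0, J * K, P)) /
    pmax(colSums(matrix(dat$M, J * K, P)), 1)
  resid <- dat$y0 - array(rep(colMeanP, each = J * K), dim = dim(dat$y0))
  s0 <- max(stats::sd(resid[obs]), 1e-3)
  if (!is.finite(s0)) s0 <- 1e-3
  jit <- function(x) if (jitterRng) x * (1 + runif(length(x), -0.1, 0.1)) else x
  state <- list(
    alpha = jit(rep(gm, P)),
    beta = if (cfg@formulation == "asymmetric") rep(1, P) else jit(rep(1, P)),
    theta = rep(0, J),
    lambda = matrix(0, J, P),
    nu = if (is.finite(cfg@fixNu)) rep(cfg@fixNu, P) else jit(rep(s0, P)),
    sigma = jit(rep(s0, P)),
    w = matrix(1, J, P),
    gamma = rep(0, K),
    xi = matrix(0, J, K),
    wxi = matrix(1, J, K),
    sigmaXi = jit(s0),
    omega = if (is.null(dat$pathIdx)) NULL else
      matrix(0, length(dat$pathways), P),
    hasShared = "shared" %in% components,
    hasSpecific = "specific" %in% components)
  state
}

.rnormVec <- function(mom) rnorm(length(mom$mean), mom$mean, mom$sd)

#' Fit the shared-component model by MCMC
#'
#' Gibbs sampler for the hierarchical decomposition of per-group mean copy
#' numbers into a shared component and group-specific deviations.  Specific
#' components carry a Student-t (4 df) prior implemented as a scale mixture
#' of normals, so all location updates are conjugate; the observation- and
#' specific-level scales (half-Normal priors, sd 100) are updated by slice
#' sampling.  When the input carries a covariate axis the adjusted
#' decomposition with covariate main effects and locus-by-covariate
#' deviations is fitted; when `config` has a `pathwayMap`, specific
#' components are centred on pathway-by-group means.
#'
#' Runs are reproducible: chain `c` is seeded with `seed + c - 1` and its
#' initial values are jittered by up to 10% so that multiple chains start
#' overdispersed.  For symmetric fits the sign non-identifiability of
#' `(beta, theta)` is resolved at storage time by flipping each kept draw so
#' that `sum(beta) >= 0`.  With two or more chains the potential scale
#' reduction factor is computed per parameter and a warning (not an error)
#' is attached when any exceeds 1.1.
#'
#' @param gc a [GroupedCounts-class] (see [aggregateCopyNumber()]).
#' @param config an [SCMConfig-class].
#' @param components model components to include; dropping `"shared"` or
#'   `"specific"` fits the corresponding reduced model.
#' @return An [SCMFit-class] with `backend = "mcmc"`.
#' @seealso [fitGaussian()] for the fast deterministic backend,
#'   [callSpecific()] for significance calls.
#' @export
fitMCMC <- function(gc, config = scmConfig(),
                    components = c("shared", "specific")) {
  stopifnot(is(gc, "GroupedCounts"), is(config, "SCMConfig"))
  dat <- .scmData(gc, config)
  if (config@formulation == "asymmetric" &&
      (config@referenceGroup < 1L || config@referenceGroup > dat$P))
    stop("referenceGroup out of range")
  kept <- (config@iterations - config@burnIn) %/% config@thin
  if (kept < 1L) stop("no draws kept; increase iterations")
  nC <- config@chains
  tNormal <- config@specificPrior == "normal"

  cn <- function(base, ids) paste0(base, "[", ids, "]")
  lamNames <- as.vector(outer(dat$loci, dat$groups,
                              function(a, b) paste0("lambda[", a, ",", b, "]")))
  draws <- list(
    alpha = array(NA_real_, c(kept, nC, dat$P),
                  dimnames = list(NULL, NULL, cn("alpha", dat$groups))),
    nu = array(NA_real_, c(kept, nC, dat$P),
               dimnames = list(NULL, NULL, cn("nu", dat$groups))))
  hasShared <- "shared" %in% components
  hasSpecific <- "specific" %in% components
  if (hasShared) {
    draws$beta <- array(NA_real_, c(kept, nC, dat$P),
                        dimnames = list(NULL, NULL, cn("beta", dat$groups)))
    draws$theta <- array(NA_real_, c(kept, nC, dat$J),
                         dimnames = list(NULL, NULL, cn("theta", dat$loci)))
  }
  if (hasSpecific) {
    draws$lambda <- array(NA_real_, c(kept, nC, dat$J * dat$P),
                          dimnames = list(NULL, NULL, lamNames))
    draws$sigma <- array(NA_real_, c(kept, nC, dat$P),
                         dimnames = list(NULL, NULL, cn("sigma", dat$groups)))
  }
  if (dat$K > 1L) {
    draws$gamma <- array(NA_real_, c(kept, nC, dat$K - 1L),
                         dimnames = list(NULL, NULL, cn("gamma", dat$covLevels[-1])))
    xiNames <- as.vector(outer(dat$loci, dat$covLevels[-1],
                               function(a, b) paste0("xi[", a, ",", b, "]")))
    draws$xi <- array(NA_real_, c(kept, nC, dat$J * (dat$K - 1L)),
                      dimnames = list(NULL, NULL, xiNames))
    draws$sigmaXi <- array(NA_real_, c(kept, nC, 1L),
                           dimnames = list(NULL, NULL, "sigmaXi"))
  }
  if (!is.null(dat$pathIdx)) {
    omNames <- as.vector(outer(dat$pathways, dat$groups,
                               function(a, b) paste0("omega[", a, ",", b, "]")))
    draws$omega <- array(NA_real_, c(kept, nC, length(dat$pathways) * dat$P),
                         dimnames = list(NULL, NULL, omNames))
  }

  freeBeta <- if (config@formulation == "asymmetric")
    setdiff(seq_len(dat$P), config@referenceGroup) else seq_len(dat$P)

  for (ch in seq_len(nC)) {
    set.seed(config@seed + ch - 1L)
    state <- .initState(dat, config, components, jitterRng = nC > 1L)
    ki <- 0L
    for (it in seq_len(config@iterations)) {
      if (hasShared) {
        state$theta <- .rnormVec(.condTheta(state, dat, config))
        mb <- .condBeta(state, dat, config)
        bNew <- rnorm(dat$P, mb$mean, mb$sd)
        state$beta[freeBeta] <- bNew[freeBeta]
      }
      if (hasSpecific) {
        ml <- .condLambda(state, dat, config)
        state$lambda <- matrix(rnorm(length(ml$mean), as.vector(ml$mean),
                                     as.vector(ml$sd)), dat$J, dat$P)
        if (!tNormal) {
          om <- .omegaMatrix(state, dat)
          state$w <- matrix(rgamma(dat$J * dat$P, shape = (.PRIOR$tdf + 1) / 2,
                                   rate = (.PRIOR$tdf +
                                           (state$lambda - om)^2 %*%
                                           diag(1 / state$sigma^2, dat$P)) / 2),
                            dat$J, dat$P)
        }
        if (!is.null(dat$pathIdx)) {
          mo <- .condOmega(state, dat, config)
          state$omega <- matrix(rnorm(length(mo$mean), as.vector(mo$mean),
                                      as.vector(mo$sd)),
                                length(dat$pathways), dat$P)
        }
      }
      if (dat$K > 1L) {
        mx <- .condXi(state, dat, config)
        xiNew <- matrix(rnorm(length(mx$mean), as.vector(mx$mean),
                              as.vector(mx$sd)), dat$J, dat$K)
        state$xi[, -1] <- xiNew[, -1]
        if (!tNormal)
          state$wxi <- matrix(rgamma(dat$J * dat$K, shape = (.PRIOR$tdf + 1) / 2,
                                     rate = (.PRIOR$tdf +
                                             state$xi^2 / state$sigmaXi^2) / 2),
                              dat$J, dat$K)
        mg <- .condGamma(state, dat, config)
        gNew <- rnorm(dat$K, mg$mean, mg$sd)
        state$gamma[-1] <- gNew[-1]
        state <- .updateSigmaXi(state, dat, config)
      }
      ma <- .condAlpha(state, dat, config)
      state$alpha <- rnorm(dat$P, ma$mean, ma$sd)
      if (!is.finite(sum(state$alpha))) stop("degenerate input: non-finite update")
      if (!is.finite(config@fixNu)) state <- .updateNu(state, dat, config)
      if (hasSpecific) state <- .updateSigma(state, dat, config)

      if (it > config@burnIn && (it - config@burnIn) %% config@thin == 0L) {
        ki <- ki + 1L
        if (ki > kept) break
        flip <- hasShared && config@formulation == "symmetric" &&
          sum(state$beta) < 0
        s <- if (flip) -1 else 1
        draws$alpha[ki, ch, ] <- state$alpha
        draws$nu[ki, ch, ] <- state$nu
        if (hasShared) {
          draws$beta[ki, ch, ] <- s * state$beta
          draws$theta[ki, ch, ] <- s * state$theta
        }
        if (hasSpecific) {
          draws$lambda[ki, ch, ] <- as.vector(state$lambda)
          draws$sigma[ki, ch, ] <- state$sigma
        }
        if (dat$K > 1L) {
          draws$gamma[ki, ch, ] <- state$gamma[-1]
          draws$xi[ki, ch, ] <- as.vector(state$xi[, -1])
          draws$sigmaXi[ki, ch, ] <- state$sigmaXi
        }
        if (!is.null(dat$pathIdx))
          draws$omega[ki, ch, ] <- as.vector(state$omega)
      }
    }
  }

  summaries <- lapply(draws, function(a) {
    m <- matrix(a, nrow = dim(a)[1] * dim(a)[2])
    list(mean = colMeans(m), sd = apply(m, 2, stats::sd))
  })
  if (!hasSpecific)
    summaries$lambda <- list(mean = rep(0, dat$J * dat$P),
                             sd = rep(0, dat$J * dat$P))
  if (!hasShared) {
    summaries$beta <- list(mean = rep(0, dat$P), sd = rep(0, dat$P))
    summaries$theta <- list(mean = rep(0, dat$J), sd = rep(0, dat$J))
  }

  diag <- numeric(0)
  if (nC >= 2L && kept >= 10L) {
    diag <- unlist(lapply(draws, function(a) {
      vapply(seq_len(dim(a)[3]), function(i) .psrfMatrix(a[, , i]), numeric(1))
    }))
    names(diag) <- unlist(lapply(draws, function(a) dimnames(a)[[3]]))
    high <- sum(diag > 1.1, na.rm = TRUE)
    if (high > 0)
      warning("PSRF above 1.1 for ", high, " parameter(s); chains may not have converged")
  }

  new("SCMFit", backend = "mcmc", samples = draws, summaries = summaries,
      diagnostics = diag, config = config, groups = dat$groups,
      loci = dat$loci, covLevels = dat$covLevels, pathways = dat$pathways,
      meta = list(kept = kept, components = components))
}
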