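# Hardy-Weinberg CNV simulator for the power study.
#
# Two locus types:
#  * "common" copy-number polymorphisms: a biallelic deletion with
#    deletion-allele frequency q gives diploid copies {0,1,2} with HWE
#    probabilities (q^2, 2q(1-q), (1-q)^2);
#  * "complex" CNVs: each haplotype carries 1 copy (wild type, prob 1-f) or
#    0/2/3 copies (each f/3); the diploid copy number is the sum of two
#    independent haplotypes, supported on {0,...,6} with mode 2.
# Group-specific association is induced by moving the variant frequency of
# the affected group on the odds scale.

#' Shift an allele frequency by an odds ratio
#'
#' Multiplies the variant-allele odds `q/(1-q)` by `or` and maps back to a
#' frequency; strictly increasing in `or`, with `or = 1` the identity.
#'
#' @param q allele (or variant-haplotype) frequency in (0, 1).
#' @param or odds ratio (> 0).
#' @return the shifted frequency.
#' @examples
#' shiftFreqByOR(0.1, 2)    # 2/11 = 0.1818...
#' @export
shiftFreqByOR <- function(q, or) {
  stopifnot(all(q > 0), all(q < 1), all(or > 0))
  o <- or * q / (1 - q)
  o / (1 + o)
}

#' HWE genotype probabilities and draws for a common (0/1/2-copy) locus
#'
#' @param q deletion-allele frequency in (0, 1).
#' @param n number of individuals to draw.
#' @return `commonCopyProbs`: probabilities of 0, 1, 2 copies;
#'   `simulateCommonLocus`: integer vector of copies.
#' @export
commonCopyProbs <- function(q) c(q^2, 2 * q * (1 - q), (1 - q)^2)

#' @rdname commonCopyProbs
#' @export
simulateCommonLocus <- function(q, n) {
  cp <- cumsum(commonCopyProbs(q))
  findInterval(runif(n), cp[1:2])
}

#' Copy-number probabilities and draws for a complex (0-6 copy) locus
#'
#' Per-haplotype copy classes are 1 (wild type, probability `1 - f`) and
#' 0, 2, 3 (each `f/3`); the diploid distribution is the exact convolution
#' of two independent haplotypes.
#'
#' @param f variant-haplotype frequency in \[0, 1).
#' @param n number of individuals to draw.
#' @return `complexCopyProbs`: probabilities of 0..6 copies;
#'   `simulateComplexLocus`: integer vector of copies.
#' @export
complexCopyProbs <- function(f) {
  h <- c(f / 3, 1 - f, f / 3, f / 3)       # copies 0..3 per haplotype
  out <- numeric(7)
  for (a in 0:3) for (b in 0:3)
    out[a + b + 1] <- out[a + b + 1] + h[a + 1] * h[b + 1]
  out
}

#' @rdname complexCopyProbs
#' @export
simulateComplexLocus <- function(f, n) {
  cp <- cumsum(complexCopyProbs(f))
  findInterval(runif(n), cp[1:6])
}

#' Describe one simulation scenario
#'
#' Defaults reproduce the package's standard power-study conditions: three
#' groups of 1000 individuals, rare variant frequencies U(0.01, 0.1), two
#' associated loci whose variant frequency in group 1 is shifted on the
#' odds scale.
#'
#' @param nGroups number of groups.
#' @param nLoci number of loci.
#' @param nAssoc number of truly associated loci.
#' @param oddsRatio variant-allele odds ratio of the affected group at the
#'   associated loci.
#' @param freqRange range of the per-locus base variant frequency (uniform).
#' @param cnvType `"common"` (copies 0-2) or `"complex"` (copies 0-6).
#' @param nPerGroup individuals per group.
#' @param reps number of simulation replicates for [runScenario()].
#' @param alpha family-wise error rate used by the decision rules.
#' @param seed integer seed.
#' @param affectedGroup index of the group carrying the association.
#' @return A [ScenarioSpec-class].
#' @export
scenarioSpec <- function(nGroups = 3, nLoci = 500, nAssoc = 2,
                         oddsRatio = 2.0, freqRange = c(0.01, 0.1),
                         cnvType = c("common", "complex"),
                         nPerGroup = 1000, reps = 100, alpha = 0.05,
                         seed = 1, affectedGroup = 1) {
  new("ScenarioSpec", nGroups = as.integer(nGroups), nLoci = as.integer(nLoci),
      nAssoc = as.integer(nAssoc), oddsRatio = as.numeric(oddsRatio),
      freqRange = as.numeric(freqRange), cnvType = match.arg(cnvType),
      nPerGroup = as.integer(nPerGroup), reps = as.integer(reps),
      alpha = as.numeric(alpha), seed = as.integer(seed),
      affectedGroup = as.integer(affectedGroup))
}

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf(paste0("ScenarioSpec: %d groups x %d, %d loci (%s), ",
                     "%d associated @ OR %.2f, freq U(%g, %g), %d reps\n"),
              object@nGroups, object@nPerGroup, object@nLoci, object@cnvType,
              object@nAssoc, object@oddsRatio, object@freqRange[1],
              object@freqRange[2], object@reps))
})

#' Simulate one copy-number dataset under a scenario
#'
#' Draws a base variant frequency per locus from the scenario's uniform
#' range; all groups share it except at the `nAssoc` associated loci, where
#' the affected group's frequency is shifted by the scenario's odds ratio.
#' Deterministic given `repSeed`.
#'
#' @param spec a [ScenarioSpec-class].
#' @param repSeed integer seed for this replicate (defaults to the
#'   scenario seed).
#' @return list with `experiment` (a [CNVExperiment-class]) and `truth`
#'   (named logical per locus, `TRUE` for associated loci).
#' @export
simulateCNVDataset <- function(spec, repSeed = spec@seed) {
  stopifnot(is(spec, "ScenarioSpec"))
  set.seed(repSeed)
  J <- spec@nLoci; P <- spec@nGroups; n <- spec@nPerGroup
  q <- runif(J, spec@freqRange[1], spec@freqRange[2])
  assoc <- sort(sample.int(J, spec@nAssoc))
  sim1 <- if (spec@cnvType == "common") simulateCommonLocus else simulateComplexLocus
  copies <- matrix(NA_integer_, J, P * n)
  for (j in seq_len(J)) {
    qv <- rep(q[j], P)
    if (j %in% assoc) qv[spec@affectedGroup] <- shiftFreqByOR(q[j], spec@oddsRatio)
    copies[j, ] <- unlist(lapply(qv, sim1, n = n), use.names = FALSE)
  }
  rownames(copies) <- sprintf("locus%04d", seq_len(J))
  group <- rep(paste0("group", seq_len(P)), each = n)
  truth <- stats::setNames(seq_len(J) %in% assoc, rownames(copies))
  list(experiment = CNVExperiment(copies, group = group), truth = truth)
}

#' Simulate aggregated data directly from the shared-component model
#'
#' Generates per-locus, per-group mean copy numbers from the model itself
#' (useful for parameter-recovery studies): `y_jp = alpha_p + beta_p theta_j
#' + lambda_jp + e_jp` with `theta_j ~ N(0, 1)` and `e_jp ~ N(0, nu_p^2)`.
#' Entries of `lambda` are taken as given (planted effects), not drawn.
#'
#' @param alpha per-group intercepts (mean copies).
#' @param beta per-group loadings of the shared component.
#' @param lambda matrix (loci x groups) of specific effects.
#' @param nu per-group observation-level sd (recycled).
#' @param seed integer seed.
#' @return A [GroupedCounts-class].
#' @export
simulateFromModel <- function(alpha, beta, lambda, nu, seed = 1) {
  set.seed(seed)
  lambda <- as.matrix(lambda)
  J <- nrow(lambda); P <- ncol(lambda)
  stopifnot(length(alpha) == P || length(alpha) == 1,
            length(beta) == P || length(beta) == 1)
  alpha <- rep(alpha, length.out = P); beta <- rep(beta, length.out = P)
  nu <- rep(nu, length.out = P)
  theta <- rnorm(J)
  y <- matrix(alpha, J, P, byrow = TRUE) + outer(theta, beta) + lambda +
    matrix(rnorm(J * P), J, P) %*% diag(nu, P)
  rownames(y) <- sprintf("locus%04d", seq_len(J))
  colnames(y) <- paste0("group", seq_len(P))
  GroupedCounts(y, n = 1L)
}
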