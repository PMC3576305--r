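#' @import methods
#' @importFrom stats dnorm dgamma pnorm qnorm pchisq rnorm rgamma runif rexp
#'   quantile var sd median optim setNames rbinom
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' CNVExperiment: integer copy-number calls with group labels
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' loci x individuals matrix of integer copy-number calls (0-6, `NA` allowed)
#' in the `"copies"` assay, with the per-individual group label (and an
#' optional categorical covariate) in `colData`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("CNVExperiment", contains = "SummarizedExperiment")

.validCNVExperiment <- function(object) {
  msg <- NULL
  if (!"copies" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'copies' is required")
  else {
    x <- SummarizedExperiment::assay(object, "copies")
    if (sum(!is.na(x)) > 0) {
      rng <- range(x, na.rm = TRUE)
      nonInt <- !is.integer(x) && any(x != round(x), na.rm = TRUE)
      if (nonInt || rng[1] < 0 || rng[2] > 6)
        msg <- c(msg, "non-missing copy values must be integers in [0, 6]")
    }
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd))
    msg <- c(msg, "colData column 'group' is required")
  else {
    g <- cd$group
    if (anyNA(g)) msg <- c(msg, "every individual needs a group label")
    if (nlevels(factor(g)) < 2) msg <- c(msg, "at least 2 groups are required")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "locus ids (rownames) must be unique")
  if (is.null(msg)) TRUE else msg
}
setValidity("CNVExperiment", .validCNVExperiment)

#' Per-locus, per-group aggregated copy numbers
#'
#' Mean copy number `y[j, k, p]` and non-missing count `n[j, k, p]` for locus
#' j, covariate level k and group p.  Without a covariate the middle axis has
#' a single level.  Cells with no data (`n = 0`) have `y = NA` and are
#' excluded from all likelihoods.
#'
#' @slot y numeric array (loci x covariate levels x groups) of mean copies.
#' @slot n integer array of the same shape counting non-missing individuals.
#' @export
setClass("GroupedCounts", representation(y = "array", n = "array"))

.validGroupedCounts <- function(object) {
  msg <- NULL
  if (!identical(dim(object@y), dim(object@n)))
    msg <- c(msg, "y and n must have identical dimensions")
  if (length(dim(object@y)) != 3L)
    msg <- c(msg, "y must be a 3-d array (loci x covariate levels x groups)")
  ok <- object@n > 0
  yv <- object@y[ok]
  if (length(yv) && (anyNA(yv) || any(yv < 0) || any(yv > 6)))
    msg <- c(msg, "y must lie in [0, 6] wherever n > 0")
  if (any(!is.na(object@y[!ok])))
    msg <- c(msg, "y must be NA wherever n = 0")
  if (is.null(msg)) TRUE else msg
}
setValidity("GroupedCounts", .validGroupedCounts)

#' Configuration for the shared-component model
#'
#' @slot formulation `"symmetric"` (all groups exchangeable) or
#'   `"asymmetric"` (loading of the reference group fixed to 1).
#' @slot referenceGroup group index used when `formulation = "asymmetric"`.
#' @slot specificPrior `"t4"` (Student-t, 4 df) or `"normal"` prior for the
#'   specific components.
#' @slot sharedVarianceFixed variance of the shared component (fixed at 1 for
#'   identifiability).
#' @slot equalGroupVariance single observation-level variance for all groups
#'   instead of one per group.
#' @slot pathwayMap optional named character vector mapping locus id to
#'   pathway; enables pathway-level means for the specific components.
#' @slot chains,iterations,burnIn,thin MCMC run lengths.
#' @slot seed integer seed.
#' @slot fixNu if finite, the observation-level standard deviation is held at
#'   this value instead of being sampled/optimised.
#' @export
setClass("SCMConfig", representation(
  formulation = "character", referenceGroup = "integer",
  specificPrior = "character", sharedVarianceFixed = "numeric",
  equalGroupVariance = "logical", pathwayMap = "character",
  chains = "integer", iterations = "integer", burnIn = "integer",
  thin = "integer", seed = "integer", fixNu = "numeric"))

.validSCMConfig <- function(object) {
  msg <- NULL
  if (!object@formulation %in% c("symmetric", "asymmetric"))
    msg <- c(msg, "formulation must be 'symmetric' or 'asymmetric'")
  if (object@formulation == "asymmetric" && length(object@referenceGroup) != 1L)
    msg <- c(msg, "referenceGroup is required for the asymmetric formulation")
  if (!object@specificPrior %in% c("t4", "normal"))
    msg <- c(msg, "specificPrior must be 't4' or 'normal'")
  if (object@iterations <= object@burnIn || object@burnIn < 0L)
    msg <- c(msg, "need iterations > burnIn >= 0")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (object@chains < 1L) msg <- c(msg, "chains must be >= 1")
  if (object@sharedVarianceFixed <= 0)
    msg <- c(msg, "sharedVarianceFixed must be positive")
  if (is.null(msg)) TRUE else msg
}
setValidity("SCMConfig", .validSCMConfig)

#' Fitted shared-component model
#'
#' Returned by [fitMCMC()] and [fitGaussian()].  For the MCMC backend,
#' `samples` holds thinned posterior draws as a named list of arrays with
#' dimensions (kept iterations, chains, coordinates); for the Gaussian
#' backend, `summaries` holds exact posterior means and standard deviations.
#'
#' @slot backend `"mcmc"` or `"gaussian"`.
#' @slot samples named list of draw arrays (MCMC backend).
#' @slot summaries named list with `mean`/`sd` per parameter (both backends;
#'   for MCMC these are Monte-Carlo summaries).
#' @slot diagnostics named numeric vector of potential scale reduction
#'   factors (MCMC backend with >= 2 chains).
#' @slot config the [SCMConfig-class] used.
#' @slot groups,loci,covLevels,pathways dimension labels.
#' @slot meta list of backend details (log marginal likelihood, ...).
#' @export
setClass("SCMFit", representation(
  backend = "character", samples = "list", summaries = "list",
  diagnostics = "numeric", config = "SCMConfig", groups = "character",
  loci = "character", covLevels = "character", pathways = "character",
  meta = "list"))

#' Simulation scenario for the CNV power study
#'
#' Describes one cell of the simulation design: number of groups and loci,
#' how many loci are truly associated and at what odds ratio, the allele
#' frequency range, the CNV type (`"common"` copies 0-2, `"complex"` copies
#' 0-6), the per-group sample size, and the number of replicates.
#'
#' @export
setClass("ScenarioSpec", representation(
  nGroups = "integer", nLoci = "integer", nAssoc = "integer",
  oddsRatio = "numeric", freqRange = "numeric", cnvType = "character",
  nPerGroup = "integer", reps = "integer", alpha = "numeric",
  seed = "integer", affectedGroup = "integer"))

.validScenarioSpec <- function(object) {
  msg <- NULL
  if (object@nAssoc > object@nLoci) msg <- c(msg, "nAssoc must be <= nLoci")
  if (object@oddsRatio <= 0) msg <- c(msg, "oddsRatio must be positive")
  fr <- object@freqRange
  if (length(fr) != 2L || fr[1] <= 0 || fr[2] >= 1 || fr[1] > fr[2])
    msg <- c(msg, "freqRange must satisfy 0 < low <= high < 1")
  if (!object@cnvType %in% c("common", "complex"))
    msg <- c(msg, "cnvType must be 'common' or 'complex'")
  if (object@nGroups < 2L) msg <- c(msg, "nGroups must be >= 2")
  if (object@affectedGroup < 1L || object@affectedGroup > object@nGroups)
    msg <- c(msg, "affectedGroup must index one of the groups")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (is.null(msg)) TRUE else msg
}
setValidity("ScenarioSpec", .validScenarioSpec)
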