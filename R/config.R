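#' Create a shared-component model configuration
#'
#' Defaults follow the package's standard analysis settings: symmetric
#' formulation (no reference group), Student-t (4 df) specific components,
#' per-group observation variances, two chains of 40,000 iterations with a
#' 10,000-iteration burn-in thinned by 10.
#'
#' @param formulation `"symmetric"` or `"asymmetric"`.
#' @param referenceGroup group index whose loading is fixed to 1
#'   (asymmetric formulation only).
#' @param specificPrior `"t4"` or `"normal"`.
#' @param sharedVarianceFixed variance of the shared component; fixed at 1
#'   for identifiability.
#' @param equalGroupVariance use a single observation-level variance for all
#'   groups.
#' @param pathwayMap optional named character vector `locus id -> pathway`;
#'   centers the specific components on pathway-by-group means.
#' @param chains,iterations,burnIn,thin MCMC run lengths.
#' @param seed integer seed (chain c uses `seed + c - 1`).
#' @param fixNu hold the observation-level standard deviation fixed at this
#'   value (`NA` = estimate it).
#' @return An [SCMConfig-class].
#' @export
scmConfig <- function(formulation = c("symmetric", "asymmetric"),
                      referenceGroup = NA_integer_,
                      specificPrior = c("t4", "normal"),
                      sharedVarianceFixed = 1,
                      equalGroupVariance = FALSE,
                      pathwayMap = NULL,
                      chains = 2L, iterations = 40000L, burnIn = 10000L,
                      thin = 10L, seed = 1L, fixNu = NA_real_) {
  formulation <- match.arg(formulation)
  new("SCMConfig", formulation = formulation,
      referenceGroup = if (formulation == "asymmetric")
        as.integer(referenceGroup) else integer(0),
      specificPrior = match.arg(specificPrior),
      sharedVarianceFixed = as.numeric(sharedVarianceFixed),
      equalGroupVariance = isTRUE(equalGroupVariance),
      pathwayMap = if (is.null(pathwayMap)) character(0) else pathwayMap,
      chains = as.integer(chains), iterations = as.integer(iterations),
      burnIn = as.integer(burnIn), thin = as.integer(thin),
      seed = as.integer(seed), fixNu = as.numeric(fixNu))
}

setMethod("show", "SCMConfig", function(object) {
  cat("SCMConfig:", object@formulation, "formulation,",
      object@specificPrior, "specific prior\n")
  cat(sprintf("chains=%d iterations=%d burnIn=%d thin=%d seed=%d\n",
              object@chains, object@iterations, object@burnIn,
              object@thin, object@seed))
})

# fixed prior scales: alpha ~ N(0, var 1000); beta ~ N(0, var 100);
# gamma_k ~ N(0, var 1000); omega_gp ~ N(0, var 100);
# nu, sigma, sigma_xi ~ half-Normal(sd 100)
.PRIOR <- list(alphaVar = 1000, betaVar = 100, gammaVar = 1000,
               omegaVar = 100, scaleSd = 100, tdf = 4)

#' @describeIn SCMFit posterior mean/sd summaries as a named list; each
#'   element has components `mean` and `sd` shaped like the parameter.
#' @param x,object an `SCMFit`.
#' @export
posteriorSummaries <- function(x) x@summaries

#' @describeIn SCMFit specific-component (lambda) summaries or draws.  With
#'   `what = "draws"` (MCMC backend) returns a matrix of pooled posterior
#'   draws, one column per (locus, group) cell in column-major (locus fastest)
#'   order.
#' @param what `"mean"`, `"sd"` or `"draws"`.
#' @export
specificEffects <- function(x, what = c("mean", "sd", "draws")) {
  what <- match.arg(what)
  if (what == "draws") {
    if (x@backend != "mcmc") stop("draws are only available for the MCMC backend")
    a <- x@samples$lambda
    matrix(a, nrow = dim(a)[1] * dim(a)[2], dimnames = list(NULL, dimnames(a)[[3]]))
  } else {
    matrix(x@summaries$lambda[[what]], nrow = length(x@loci),
           dimnames = list(x@loci, x@groups))
  }
}

#' @describeIn SCMFit potential scale reduction factors per parameter
#'   (MCMC backend fitted with at least two chains).
#' @export
psrf <- function(x) x@diagnostics

setMethod("show", "SCMFit", function(object) {
  cat("SCMFit (", object@backend, " backend): ", length(object@loci),
      " loci x ", length(object@groups), " groups\n", sep = "")
  s <- object@summaries
  cat("alpha:", paste(sprintf("%s=%.3f", object@groups, s$alpha$mean),
                      collapse = " "), "\n")
  cat("beta: ", paste(sprintf("%.3f", s$beta$mean), collapse = " "), "\n")
  cat("nu:   ", paste(sprintf("%.4f", s$nu$mean), collapse = " "), "\n")
  if (length(object@diagnostics))
    cat("max PSRF:", sprintf("%.3f", max(object@diagnostics)), "\n")
})
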