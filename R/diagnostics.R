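# Gelman-Rubin potential scale reduction factor.
#
# With m chains of n kept draws, W = mean of the per-chain sample variances
# and B = n * variance of the chain means; the PSRF reported here is
# sqrt((W + B/n) / W), the ratio of the pooled variance estimate to the
# within-chain variance.  It equals 1 exactly when the chains coincide and
# grows with any between-chain disagreement.

.psrfMatrix <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt((W + B / n) / W)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor (PSRF) per scalar parameter, comparing
#' within- to between-chain variability.  Values near 1 indicate that the
#' chains have mixed; values above ~1.1 are conventionally taken as signs of
#' non-convergence.
#'
#' @param x an [SCMFit-class] from [fitMCMC()] run with at least two chains,
#'   or a numeric matrix of draws with one column per chain.
#' @return Named numeric vector (or scalar for a matrix) of PSRF values.
#' @examples
#' ch <- cbind(rnorm(200), rnorm(200))
#' gelmanRubin(ch)
#' @export
setGeneric("gelmanRubin", function(x) standardGeneric("gelmanRubin"))

#' @rdname gelmanRubin
#' @export
setMethod("gelmanRubin", "matrix", function(x) {
  if (ncol(x) < 2L) stop("at least 2 chains are required")
  if (nrow(x) < 10L) stop("at least 10 kept draws per chain are required")
  .psrfMatrix(x)
})

#' @rdname gelmanRubin
#' @export
setMethod("gelmanRubin", "SCMFit", function(x) {
  if (x@backend != "mcmc")
    stop("convergence diagnostics apply to the MCMC backend only")
  nC <- dim(x@samples[[1]])[2]
  if (nC < 2L) stop("at least 2 chains are required")
  if (dim(x@samples[[1]])[1] < 10L)
    stop("at least 10 kept draws per chain are required")
  out <- unlist(lapply(x@samples, function(a)
    vapply(seq_len(dim(a)[3]), function(i) .psrfMatrix(a[, , i]), numeric(1))))
  names(out) <- unlist(lapply(x@samples, function(a) dimnames(a)[[3]]))
  out
})
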