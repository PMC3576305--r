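# Significance calls for the specific components.
#
# Three criteria, all applied at a Bonferroni-corrected credible level
# 1 - alpha/c (c = number of loci): equal-tail quantile intervals from MCMC
# draws, normal-approximation intervals from posterior mean/sd, and the
# posterior tail probability min(P(lambda > 0), P(lambda < 0)) compared with
# alpha/(2c).  A (locus, group) cell is a gain when significantly above 0
# and a loss when significantly below.

.directions <- function(sig, lo, hi) {
  ifelse(sig & lo > 0, "gain", ifelse(sig & hi < 0, "loss", "none"))
}

#' Equal-tail credible-interval calls from posterior draws
#'
#' @param draws numeric matrix of posterior draws (rows) per cell (columns),
#'   or a vector for a single cell.
#' @param level credible level in (0, 1), e.g. [bonferroniLevel()] output.
#' @return data.frame with `estimate` (posterior median), `lower`, `upper`,
#'   `significant`, `direction`.
#' @details Estimating the extreme tail quantiles that a Bonferroni-level
#'   interval needs is hard from Monte-Carlo output: when fewer than
#'   `10 / (1 - level)` draws are available a warning recommends the
#'   normal-approximation rule ([decideNormal()]).
#' @export
decideQuantile <- function(draws, level) {
  stopifnot(level > 0, level < 1)
  draws <- as.matrix(draws)
  if (nrow(draws) == 0L) stop("no draws")
  if (nrow(draws) < 10 / (1 - level))
    warning(sprintf(paste("only %d draws for a %.6f-level interval;",
                          "extreme tail quantiles are unstable -",
                          "consider the normal-approximation criterion"),
                    nrow(draws), level))
  a <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
  lo <- qs[1, ]; md <- qs[2, ]; hi <- qs[3, ]
  sig <- lo > 0 | hi < 0
  data.frame(estimate = md, lower = lo, upper = hi, significant = sig,
             direction = .directions(sig, lo, hi), stringsAsFactors = FALSE)
}

#' Normal-approximation credible-interval calls
#'
#' Interval `mean +/- z * sd` with `z` the standard-normal quantile at
#' `(1 + level)/2`; significant when the interval excludes 0.  A degenerate
#' cell (`sd = 0`) is significant iff its mean is non-zero.
#'
#' @param mean,sd posterior means and standard deviations (vectors).
#' @param level credible level in (0, 1).
#' @return data.frame as in [decideQuantile()].
#' @export
decideNormal <- function(mean, sd, level) {
  stopifnot(level > 0, level < 1, length(mean) == length(sd), all(sd >= 0))
  z <- qnorm((1 + level) / 2)
  lo <- mean - z * sd; hi <- mean + z * sd
  sig <- ifelse(sd == 0, mean != 0, lo > 0 | hi < 0)
  data.frame(estimate = mean, lower = lo, upper = hi, significant = sig,
             direction = .directions(sig, lo, hi), stringsAsFactors = FALSE)
}

#' Posterior tail-probability calls
#'
#' The tail probability `q = min(P(lambda > 0), P(lambda < 0))` is estimated
#' from the draws and compared with the two-sided Bonferroni-matched
#' threshold `alpha / (2 * nLoci)`, so that all three decision criteria
#' target the same family-wise error rate.
#'
#' @inheritParams decideQuantile
#' @param alpha family-wise error rate.
#' @param nLoci number of loci tested.
#' @return data.frame with `estimate` (posterior median), `tailProb`,
#'   `significant`, `direction`.
#' @export
decidePosteriorProb <- function(draws, alpha = 0.05, nLoci) {
  draws <- as.matrix(draws)
  if (nrow(draws) == 0L) stop("no draws")
  pPos <- colMeans(draws > 0)
  pNeg <- colMeans(draws < 0)
  q <- pmin(pPos, pNeg)
  md <- apply(draws, 2, stats::median)
  sig <- q < alpha / (2 * nLoci)
  dir <- ifelse(sig & md > 0, "gain", ifelse(sig & md < 0, "loss", "none"))
  data.frame(estimate = md, tailProb = q, significant = sig, direction = dir,
             stringsAsFactors = FALSE)
}

#' Call group-specific loci from a fitted shared-component model
#'
#' Applies one of the three decision criteria to every (locus, group)
#' specific component at the Bonferroni-corrected credible level
#' `bonferroniLevel(nLoci, alpha)`.  For the Gaussian backend the posterior
#' is exactly normal, so the `"quantile"` and `"normal"` criteria coincide
#' (exact equal-tail normal quantiles) and `"prob"` uses the exact normal
#' tail probability.
#'
#' @param fit an [SCMFit-class].
#' @param alpha family-wise error rate (default 0.05).
#' @param criterion `"quantile"`, `"normal"` or `"prob"`.
#' @param level credible level; defaults to `bonferroniLevel` over the
#'   fitted loci.
#' @return data.frame with one row per (locus, group): `locus`, `group`,
#'   `estimate`, interval bounds or `tailProb`, `significant`, `direction`
#'   (`gain`/`loss`/`none`), `criterion`, `level`.
#' @export
callSpecific <- function(fit, alpha = 0.05,
                         criterion = c("quantile", "normal", "prob"),
                         level = NULL) {
  stopifnot(is(fit, "SCMFit"))
  criterion <- match.arg(criterion)
  J <- length(fit@loci); P <- length(fit@groups)
  if (is.null(level)) level <- bonferroniLevel(J, alpha)
  gaussian <- fit@backend == "gaussian"
  if (gaussian || criterion == "normal") {
    m <- fit@summaries$lambda$mean; s <- fit@summaries$lambda$sd
    if (criterion == "prob") {
      zq <- ifelse(s > 0, pnorm(-abs(m) / s), ifelse(m == 0, 0.5, 0))
      res <- data.frame(estimate = m, tailProb = zq,
                        significant = zq < alpha / (2 * J),
                        stringsAsFactors = FALSE)
      res$direction <- ifelse(res$significant & m > 0, "gain",
                              ifelse(res$significant & m < 0, "loss", "none"))
    } else {
      res <- decideNormal(m, s, level)
    }
  } else {
    draws <- specificEffects(fit, "draws")
    res <- if (criterion == "quantile") decideQuantile(draws, level)
    else decidePosteriorProb(draws, alpha, J)
  }
  out <- data.frame(locus = rep(fit@loci, times = P),
                    group = rep(fit@groups, each = J),
                    res, criterion = criterion, level = level,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' True positive and true negative rates of a decision table
#'
#' A locus counts as detected when its specific component is significant in
#' any group.  TPR is the percentage of truly associated loci detected; TNR
#' the percentage of truly null loci left undetected.
#'
#' @param decisions a decision data.frame from [callSpecific()] (or any
#'   data.frame with `locus` and `significant` columns), or a named logical
#'   vector of per-locus detections.
#' @param truth named logical vector: `TRUE` for truly associated loci.
#'   Must cover every locus in `decisions`.
#' @return named numeric vector `c(TPR, TNR)` in percent; TPR is `NA` when
#'   no locus is truly associated.
#' @examples
#' truth <- c(a = TRUE, b = FALSE, c = FALSE)
#' det <- c(a = TRUE, b = FALSE, c = TRUE)
#' confusionRates(det, truth)   # TPR 100, TNR 50
#' @export
confusionRates <- function(decisions, truth) {
  if (is.data.frame(decisions)) {
    det <- tapply(decisions$significant, decisions$locus, any)
  } else det <- decisions
  loci <- names(det)
  if (is.null(loci) || !all(loci %in% names(truth)))
    stop("truth must be a named logical covering every locus")
  tr <- truth[loci]
  nA <- sum(tr)
  tpr <- if (nA == 0) NA_real_ else 100 * sum(det & tr) / nA
  tnr <- if (nA == length(tr)) NA_real_ else 100 * sum(!det & !tr) / sum(!tr)
  c(TPR = tpr, TNR = tnr)
}
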