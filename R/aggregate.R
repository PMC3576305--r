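#' Aggregate individual copy numbers to per-group means
#'
#' Computes, for every locus and group (and covariate level when the
#' experiment carries one), the mean copy number over individuals with a
#' non-missing call and the number of such individuals.  Cells with no data
#' are flagged (`NA` mean, count 0) with a warning and are excluded from all
#' model likelihoods downstream.
#'
#' @param x a [CNVExperiment-class].
#' @param useCovariate aggregate over group x covariate cells (requires a
#'   covariate in `x`); default `TRUE` whenever a covariate is present.
#' @return A [GroupedCounts-class].
#' @examples
#' ce <- CNVExperiment(matrix(c(0L, 1L, 2L, NA), nrow = 1), group = rep(1:2, each = 2))
#' groupMeans(aggregateCopyNumber(ce))
#' @export
aggregateCopyNumber <- function(x, useCovariate = !is.null(covariateLabels(x))) {
  copies <- copyNumbers(x)
  g <- groupLabels(x)
  cv <- if (useCovariate) covariateLabels(x) else NULL
  if (useCovariate && is.null(cv)) stop("no covariate present in 'x'")
  if (is.null(cv)) cv <- factor(rep("all", ncol(copies)))
  cell <- interaction(cv, g, sep = "\r", lex.order = FALSE)
  ind <- stats::model.matrix(~ 0 + cell)            # individuals x cells
  obs <- !is.na(copies)
  c0 <- copies; c0[!obs] <- 0L
  n <- obs %*% ind
  s <- c0 %*% ind
  y <- ifelse(n > 0, s / n, NA_real_)
  J <- nrow(copies); K <- nlevels(cv); P <- nlevels(g)
  dn <- list(rownames(copies), levels(cv), levels(g))
  gc <- new("GroupedCounts",
            y = array(as.numeric(y), dim = c(J, K, P), dimnames = dn),
            n = array(as.integer(n), dim = c(J, K, P), dimnames = dn))
  nEmpty <- sum(gc@n == 0)
  if (nEmpty > 0)
    warning(nEmpty, " empty (locus, group) cell(s); excluded from the likelihood")
  gc
}

#' Construct a GroupedCounts object directly
#'
#' Mainly useful for model-level simulations where aggregated means are
#' generated without an individual-level matrix.
#'
#' @param y matrix (loci x groups) or 3-d array (loci x covariate levels x
#'   groups) of mean copy numbers.
#' @param n matching counts of non-missing individuals; a scalar is recycled.
#' @return A [GroupedCounts-class].
#' @export
GroupedCounts <- function(y, n = 1L) {
  if (length(dim(y)) == 2L) {
    dn <- dimnames(y)
    if (is.null(dn)) dn <- list(NULL, NULL)
    if (is.null(dn[[1]])) dn[[1]] <- paste0("locus", seq_len(nrow(y)))
    if (is.null(dn[[2]])) dn[[2]] <- paste0("group", seq_len(ncol(y)))
    y <- array(as.numeric(y), dim = c(nrow(y), 1L, length(dn[[2]])),
               dimnames = list(dn[[1]], "all", dn[[2]]))
  }
  if (length(n) == 1L) n <- array(as.integer(n), dim = dim(y))
  if (length(dim(n)) == 2L) n <- array(as.integer(n), dim = dim(y))
  dimnames(n) <- dimnames(y)
  storage.mode(n) <- "integer"
  y[n == 0] <- NA_real_
  new("GroupedCounts", y = y, n = n)
}

#' @describeIn GroupedCounts mean copies; a loci x groups matrix when there
#'   is no covariate axis, otherwise the full 3-d array.
#' @param x a `GroupedCounts`.
#' @param drop collapse a singleton covariate axis (default `TRUE`).
#' @export
groupMeans <- function(x, drop = TRUE) .dropCov(x@y, drop)

#' @describeIn GroupedCounts non-missing counts, same shape as `groupMeans`.
#' @export
cellCounts <- function(x, drop = TRUE) .dropCov(x@n, drop)

#' @describeIn GroupedCounts group names.
#' @export
groupNames <- function(x) dimnames(x@y)[[3]]

#' @describeIn GroupedCounts covariate level names.
#' @export
covariateLevels <- function(x) dimnames(x@y)[[2]]

.dropCov <- function(a, drop) {
  if (drop && dim(a)[2] == 1L) {
    m <- a[, 1L, , drop = FALSE]
    dim(m) <- dim(a)[c(1L, 3L)]
    dimnames(m) <- dimnames(a)[c(1L, 3L)]
    m
  } else a
}

setMethod("show", "GroupedCounts", function(object) {
  d <- dim(object@y)
  cat("GroupedCounts:", d[1], "loci x", d[3], "groups",
      if (d[2] > 1L) paste("x", d[2], "covariate levels") else "", "\n")
  cat("groups:", paste(groupNames(object), collapse = ", "), "\n")
  if (any(object@n == 0)) cat("empty cells:", sum(object@n == 0), "\n")
})

#' Bonferroni-corrected credible level
#'
#' The credible level `1 - alpha / nLoci` at which per-locus intervals
#' control the family-wise error rate at `alpha` across `nLoci` tests.
#' Computed exactly, without rounding.
#'
#' @param nLoci number of loci tested (>= 1).
#' @param alpha family-wise error rate in (0, 1); default 0.05.
#' @return The credible level in (0, 1).
#' @examples
#' bonferroniLevel(8587)        # 0.9999942, i.e. 99.9994%
#' bonferroniLevel(1)           # 0.95
#' @export
bonferroniLevel <- function(nLoci, alpha = 0.05) {
  if (length(nLoci) != 1L || is.na(nLoci) || nLoci < 1 || nLoci != round(nLoci))
    stop("nLoci must be a positive integer")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  1 - alpha / nLoci
}
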