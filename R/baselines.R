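# Per-locus baseline association tests.
#
# All three operate on one locus at a time: copy-number category counts per
# group.  They are implemented from first principles on the count table
# (fast enough to run hundreds of thousands of times inside power studies)
# and are cross-checked against stats::chisq.test / stats::kruskal.test /
# nnet::multinom in the test suite.

#' Pearson chi-square test on a copy-number x group contingency table
#'
#' Rows or columns that are entirely zero are dropped before testing.  A
#' table that degenerates to a single row or column has no association left
#' to test: the result is flagged degenerate with `statistic = 0`, `df = 0`,
#' `p = 1`.
#'
#' @param tab integer matrix of counts, copy-number categories x groups.
#' @return list with `statistic`, `df`, `p.value`, `degenerate`.
#' @examples
#' chisqTestTable(matrix(c(10, 20, 20, 10), 2))  # X2 = 20/3, df = 1
#' @export
chisqTestTable <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(statistic = 0, df = 0L, p.value = 1, degenerate = TRUE))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df, p.value = pchisq(stat, df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Kruskal-Wallis test with mid-rank ties correction
#'
#' Copy-number data are massively tied (a handful of integer values across
#' thousands of individuals), so the statistic is computed from the category
#' counts using mid-ranks and always divided by the ties correction factor
#' `1 - sum(t^3 - t) / (N^3 - N)`.
#'
#' @param x copy numbers (or any ordinal values) per individual, or a counts
#'   matrix (categories x groups) via `counts`.
#' @param g group label per individual (ignored when `counts` is given).
#' @param counts optional categories x groups count matrix; rows must be in
#'   increasing value order.
#' @return list with `statistic` (H), `df`, `p.value`.
#' @examples
#' kruskalWallisTest(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))  # H = 3.857
#' @export
kruskalWallisTest <- function(x, g = NULL, counts = NULL) {
  if (is.null(counts)) {
    keep <- !is.na(x) & !is.na(g)
    x <- x[keep]; g <- factor(g[keep])
    if (nlevels(g) < 2L) stop("at least 2 groups are required")
    counts <- table(factor(x), g)
  }
  counts <- as.matrix(counts)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  P <- ncol(counts)
  if (P < 2L) stop("at least 2 non-empty groups are required")
  Nv <- rowSums(counts)
  N <- sum(Nv)
  if (N < 2L) stop("too few observations")
  midrank <- cumsum(Nv) - Nv + (Nv + 1) / 2
  R <- colSums(counts * midrank)
  np <- colSums(counts)
  H <- 12 / (N * (N + 1)) * sum(R^2 / np) - 3 * (N + 1)
  tieAdj <- 1 - sum(Nv^3 - Nv) / (N^3 - N)
  if (tieAdj <= 0) {             # all observations identical
    return(list(statistic = 0, df = P - 1L, p.value = 1))
  }
  H <- H / tieAdj
  list(statistic = H, df = P - 1L,
       p.value = pchisq(H, P - 1L, lower.tail = FALSE))
}

#' Multinomial logistic likelihood-ratio test of group vs copy number
#'
#' Baseline-category logit model with the group as the outcome (reference:
#' first group) and the copy number as a single numeric predictor (default)
#' or as a categorical factor.  The null (intercept-only) model has the
#' closed-form maximum `sum(n_p log(n_p / n))`; the full model is fitted by
#' Newton-Raphson with step halving on the collapsed (value, group) counts.
#' The likelihood-ratio statistic is referred to a chi-square with
#' `P - 1` df (numeric coding) or `(P - 1)(L - 1)` df (categorical,
#' L copy levels).
#'
#' Quasi-separation (diverging coefficients or a failed fit) is flagged and
#' returns the conservative `p = 1` with a warning, so that large simulation
#' sweeps over rare-allele replicates stay well defined.
#'
#' @param x copy number per individual.
#' @param g group label per individual.
#' @param coding `"numeric"` (default) or `"categorical"`.
#' @return list with `statistic` (LR), `df`, `p.value`, `logLik`,
#'   `logLikNull`, `converged`.
#' @export
multinomLRTest <- function(x, g, coding = c("numeric", "categorical")) {
  coding <- match.arg(coding)
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- factor(g[keep])
  P <- nlevels(g)
  if (P < 2L) stop("at least 2 groups are required")
  vals <- sort(unique(x))
  cnt <- as.matrix(table(factor(x, levels = vals), g))  # L x P
  np <- colSums(cnt); n <- sum(np)
  ll0 <- sum(np * log(np / n))
  if (length(vals) < 2L)
    return(list(statistic = 0, df = 0L, p.value = 1, logLik = ll0,
                logLikNull = ll0, converged = TRUE))
  X <- if (coding == "numeric") cbind(1, vals)
  else cbind(1, stats::model.matrix(~ factor(vals))[, -1, drop = FALSE])
  L <- nrow(X); q <- ncol(X)
  npar <- q * (P - 1L)
  theta <- rep(0, npar)                 # column-major: q coefs per group 2..P
  rowTot <- rowSums(cnt)
  loglik <- function(theta) {
    eta <- cbind(0, X %*% matrix(theta, q, P - 1L))
    eta <- eta - apply(eta, 1, max)
    lp <- eta - log(rowSums(exp(eta)))
    sum(cnt * lp)
  }
  score_hess <- function(theta) {
    eta <- cbind(0, X %*% matrix(theta, q, P - 1L))
    eta <- eta - apply(eta, 1, max)
    pr <- exp(eta); pr <- pr / rowSums(pr)           # L x P
    resid <- cnt[, -1, drop = FALSE] - rowTot * pr[, -1, drop = FALSE]
    gr <- as.vector(crossprod(X, resid))
    H <- matrix(0, npar, npar)
    for (a in seq_len(P - 1L)) for (b in seq_len(P - 1L)) {
      wab <- rowTot * (pr[, a + 1] * ((a == b) - pr[, b + 1]))
      H[(a - 1) * q + seq_len(q), (b - 1) * q + seq_len(q)] <-
        -crossprod(X, X * wab)
    }
    list(gr = gr, H = H)
  }
  ll <- loglik(theta); converged <- FALSE
  for (it in seq_len(100L)) {
    sh <- score_hess(theta)
    step <- tryCatch(solve(sh$H + diag(1e-10, npar), -sh$gr),
                     error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      thNew <- theta + lam * step
      llNew <- loglik(thNew)
      if (is.finite(llNew) && llNew >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    if (lam < 1e-8) break
    improve <- llNew - ll
    theta <- thNew; ll <- llNew
    if (max(abs(sh$gr)) < 1e-8 || improve < 1e-12) { converged <- TRUE; break }
  }
  if (!converged || max(abs(theta)) > 30) {
    warning("multinomial fit flagged (non-convergence or quasi-separation); p set to 1")
    return(list(statistic = NA_real_, df = NA_integer_, p.value = 1,
                logLik = ll, logLikNull = ll0, converged = FALSE))
  }
  stat <- 2 * (ll - ll0)
  df <- if (coding == "numeric") P - 1L else (P - 1L) * (length(vals) - 1L)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE),
       logLik = ll, logLikNull = ll0, converged = TRUE)
}

#' Per-locus baseline p-values for a copy-number experiment
#'
#' Runs one of the baseline tests at every locus of a [CNVExperiment-class]
#' and returns the vector of p-values (used by [runScenario()] with
#' Bonferroni correction).
#'
#' @param x a [CNVExperiment-class].
#' @param method `"chisq"`, `"kruskal"` or `"multinom"`.
#' @param coding predictor coding for the multinomial test.
#' @return named numeric vector of p-values, one per locus.
#' @export
baselinePValues <- function(x, method = c("chisq", "kruskal", "multinom"),
                            coding = "numeric") {
  method <- match.arg(method)
  copies <- copyNumbers(x)
  g <- groupLabels(x)
  J <- nrow(copies)
  out <- numeric(J)
  gi <- as.integer(g); P <- nlevels(g)
  for (j in seq_len(J)) {
    cj <- copies[j, ]
    ok <- !is.na(cj)
    tab <- .countTable(cj[ok], gi[ok], P)
    out[j] <- switch(method,
      chisq = chisqTestTable(tab)$p.value,
      kruskal = kruskalWallisTest(counts = tab)$p.value,
      multinom = multinomLRTest(cj[ok], g[ok], coding = coding)$p.value)
  }
  names(out) <- rownames(copies)
  out
}

# counts by (copy value, group); rows ordered by increasing value
.countTable <- function(v, gi, P) {
  vals <- sort(unique(v))
  vi <- match(v, vals)
  matrix(tabulate(vi + (gi - 1L) * length(vals), nbins = length(vals) * P),
         length(vals), P)
}
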