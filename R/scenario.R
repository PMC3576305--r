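#' Run a simulation scenario and score every method
#'
#' For each replicate: simulate a dataset with [simulateCNVDataset()], run
#' the requested methods, call loci at the Bonferroni-corrected threshold
#' (`alpha / nLoci` for baseline p-values, `bonferroniLevel(nLoci, alpha)`
#' credible level for the Bayesian criteria), and score detections against
#' the simulation truth with [confusionRates()].  A locus counts as
#' detected by the Bayesian model when its specific component is
#' significant in any group.
#'
#' Replicate seeds are derived deterministically from the scenario seed, so
#' the full table is bit-reproducible.  A method failing on a replicate is
#' logged and excluded for that method only.
#'
#' @param spec a [ScenarioSpec-class].
#' @param methods subset of `"bayes"`, `"chisq"`, `"kruskal"`,
#'   `"multinom"`.
#' @param criteria decision criteria to evaluate for the Bayesian model.
#' @param backend `"gaussian"` (default, deterministic and fast) or
#'   `"mcmc"` for the Bayesian fits.
#' @param config optional [SCMConfig-class] for the Bayesian fits.
#' @param extraMethods named list of functions `f(sim)` returning a named
#'   logical vector of per-locus detections; `sim` is the
#'   [simulateCNVDataset()] result.  Used e.g. to inject an oracle.
#' @return data.frame with one row per method (x criterion for the Bayesian
#'   model): mean TPR and TNR in percent with Monte-Carlo standard errors,
#'   replicates used and failures.  The per-replicate rates are attached as
#'   `attr(, "perRep")`.
#' @export
runScenario <- function(spec, methods = c("bayes", "chisq", "kruskal"),
                        criteria = "quantile",
                        backend = c("gaussian", "mcmc"), config = NULL,
                        extraMethods = NULL) {
  stopifnot(is(spec, "ScenarioSpec"))
  backend <- match.arg(backend)
  methods <- match.arg(methods, c("bayes", "chisq", "kruskal", "multinom"),
                       several.ok = TRUE)
  if (is.null(config))
    config <- scmConfig(
      specificPrior = if (backend == "gaussian") "normal" else "t4",
      seed = spec@seed)
  set.seed(spec@seed)
  repSeeds <- sample.int(.Machine$integer.max, spec@reps)
  labels <- c(setdiff(methods, "bayes"),
              if ("bayes" %in% methods) paste0("bayes:", criteria),
              names(extraMethods))
  tpr <- tnr <- matrix(NA_real_, spec@reps, length(labels),
                       dimnames = list(NULL, labels))
  fails <- stats::setNames(integer(length(labels)), labels)
  pth <- spec@alpha / spec@nLoci
  for (r in seq_len(spec@reps)) {
    sim <- simulateCNVDataset(spec, repSeed = repSeeds[r])
    scoreOne <- function(label, detFun) {
      res <- tryCatch(suppressWarnings(detFun()), error = function(e) NULL)
      if (is.null(res)) { fails[label] <<- fails[label] + 1L; return(invisible()) }
      tpr[r, label] <<- res["TPR"]; tnr[r, label] <<- res["TNR"]
    }
    for (m in setdiff(methods, "bayes"))
      scoreOne(m, function() {
        p <- baselinePValues(sim$experiment, method = m)
        confusionRates(p < pth, sim$truth)
      })
    if ("bayes" %in% methods) {
      fit <- tryCatch(suppressWarnings({
        gc <- aggregateCopyNumber(sim$experiment)
        if (backend == "gaussian") fitGaussian(gc, config)
        else fitMCMC(gc, config)
      }), error = function(e) NULL)
      for (cr in criteria) {
        lab <- paste0("bayes:", cr)
        if (is.null(fit)) { fails[lab] <- fails[lab] + 1L; next }
        scoreOne(lab, function()
          confusionRates(callSpecific(fit, alpha = spec@alpha, criterion = cr),
                         sim$truth))
      }
    }
    for (nm in names(extraMethods))
      scoreOne(nm, function() confusionRates(extraMethods[[nm]](sim), sim$truth))
  }
  mcse <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  }
  out <- data.frame(
    method = labels,
    TPR = colMeans(tpr, na.rm = TRUE), TPR_se = apply(tpr, 2, mcse),
    TNR = colMeans(tnr, na.rm = TRUE), TNR_se = apply(tnr, 2, mcse),
    reps = colSums(!is.na(tpr) | !is.na(tnr)), failures = fails,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "perRep") <- list(TPR = tpr, TNR = tnr)
  out
}
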