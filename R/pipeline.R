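# End-to-end drivers: file in, results directory out.

.prepareOutDir <- function(outDir, force) {
  if (dir.exists(outDir)) {
    if (!force && length(list.files(outDir)) > 0)
      stop("output directory ", outDir, " is not empty; use force = TRUE")
  } else dir.create(outDir, recursive = TRUE)
  invisible(outDir)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit the shared-component model on a copy-number table and write results
#'
#' Reads a copy-number table, aggregates it to per-group means, fits the
#' chosen backend, applies the chosen decision criterion at the
#' Bonferroni-corrected credible level, and writes into `outDir`:
#' `decisions.tsv` (per locus and group: posterior median, interval,
#' significance, gain/loss direction), `summary.tsv` (group-level
#' parameters), `diagnostics.tsv` (PSRF, MCMC backend), `config.json`
#' (the effective configuration, including the seed), and optionally
#' `specific_effects.pdf`.
#'
#' Everything written is reconstructible from the input file, the
#' configuration and the seed; running twice with the same seed produces
#' byte-identical tables.
#'
#' @param copiesFile path to a table readable by [readCopyNumberTable()].
#' @param outDir output directory (created; refuses to overwrite a
#'   non-empty directory unless `force`).
#' @param groupCol,idCol,covariateCol,missingToken column names and missing
#'   token of the input table.
#' @param backend `"gaussian"` or `"mcmc"`.
#' @param criterion decision criterion, see [callSpecific()].
#' @param alpha family-wise error rate for the Bonferroni level.
#' @param seed integer seed.
#' @param config optional [SCMConfig-class]; defaults follow the backend.
#' @param force overwrite a non-empty output directory.
#' @param plot write the per-group specific-component plot (PDF).
#' @return Invisibly, a list with the fit, the decision table and `outDir`.
#' @export
cnvFit <- function(copiesFile, outDir, groupCol = "group", idCol = "id",
                   covariateCol = NULL, missingToken = "NA",
                   backend = c("gaussian", "mcmc"),
                   criterion = c("quantile", "normal", "prob"),
                   alpha = 0.05, seed = 1, config = NULL, force = FALSE,
                   plot = FALSE) {
  backend <- match.arg(backend)
  criterion <- match.arg(criterion)
  .prepareOutDir(outDir, force)
  ce <- readCopyNumberTable(copiesFile, missingToken = missingToken,
                            idCol = idCol, groupCol = groupCol,
                            covariateCol = covariateCol)
  gc <- aggregateCopyNumber(ce)
  if (is.null(config))
    config <- scmConfig(
      specificPrior = if (backend == "gaussian") "normal" else "t4",
      seed = seed)
  fit <- if (backend == "gaussian") fitGaussian(gc, config)
  else fitMCMC(gc, config)
  J <- length(fit@loci)
  level <- bonferroniLevel(J, alpha)
  dec <- callSpecific(fit, alpha = alpha, criterion = criterion, level = level)

  out <- data.frame(locus_id = dec$locus, group = dec$group,
                    posterior_median = dec$estimate,
                    ci_low = if ("lower" %in% names(dec)) dec$lower else NA,
                    ci_high = if ("upper" %in% names(dec)) dec$upper else NA,
                    significant = dec$significant, direction = dec$direction)
  .writeTsv(out, file.path(outDir, "decisions.tsv"))

  s <- fit@summaries
  P <- length(fit@groups)
  .writeTsv(data.frame(group = fit@groups,
                       alpha_mean = s$alpha$mean, alpha_sd = s$alpha$sd,
                       beta_mean = s$beta$mean, nu_mean = s$nu$mean,
                       sigma_mean = s$sigma$mean),
            file.path(outDir, "summary.tsv"))
  if (length(fit@diagnostics))
    .writeTsv(data.frame(parameter = names(fit@diagnostics),
                         psrf = unname(fit@diagnostics)),
              file.path(outDir, "diagnostics.tsv"))
  cfgEcho <- list(input = copiesFile, backend = backend, criterion = criterion,
                  alpha = alpha, credibleLevel = level, seed = config@seed,
                  formulation = config@formulation,
                  specificPrior = config@specificPrior,
                  chains = config@chains, iterations = config@iterations,
                  burnIn = config@burnIn, thin = config@thin,
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(cfgEcho, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (plot) {
    grDevices::pdf(file.path(outDir, "specific_effects.pdf"),
                   width = 8, height = 2.5 * P)
    plotSpecificEffects(fit, decisions = dec)
    grDevices::dev.off()
  }
  invisible(list(fit = fit, decisions = dec, outDir = outDir))
}

#' Plot specific components per group
#'
#' One panel per group: posterior medians of the specific components with
#' their credible segments, significant gains in red and losses in blue.
#'
#' @param fit an [SCMFit-class].
#' @param decisions optional decision table from [callSpecific()]; computed
#'   at the Bonferroni level when missing.
#' @param alpha family-wise error rate used when `decisions` is missing.
#' @return Invisibly, the decision table plotted.
#' @export
plotSpecificEffects <- function(fit, decisions = NULL, alpha = 0.05) {
  if (is.null(decisions))
    decisions <- callSpecific(fit, alpha = alpha, criterion = "normal")
  groups <- fit@groups
  op <- graphics::par(mfrow = c(length(groups), 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(op))
  hasCI <- all(c("lower", "upper") %in% names(decisions))
  for (g in groups) {
    d <- decisions[decisions$group == g, ]
    cols <- ifelse(d$direction == "gain", "red",
                   ifelse(d$direction == "loss", "blue", "grey40"))
    ylim <- if (hasCI) range(d$lower, d$upper, 0) else range(d$estimate, 0)
    graphics::plot(seq_len(nrow(d)), d$estimate, pch = 16, col = cols,
                   cex = 0.6, ylim = ylim, xlab = "", ylab = "specific effect",
                   main = g)
    if (hasCI)
      graphics::segments(seq_len(nrow(d)), d$lower, seq_len(nrow(d)),
                         d$upper, col = cols)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(decisions)
}

#' Run a grid of simulation scenarios and write a benchmark table
#'
#' Convenience wrapper around [runScenario()]: evaluates every scenario in
#' `scenarios`, stacks the TPR/TNR summaries into one table (one row block
#' per scenario, Monte-Carlo standard errors included; `NA` when a scenario
#' has a single replicate) and writes it to `outDir/benchmark.tsv` together
#' with a JSON echo of the grid.
#'
#' @param scenarios list of [ScenarioSpec-class] objects (named or not).
#' @param outDir output directory.
#' @param methods,criteria,backend,config,extraMethods passed to
#'   [runScenario()].
#' @param force overwrite a non-empty output directory.
#' @return Invisibly, the combined benchmark data.frame.
#' @export
cnvBenchmark <- function(scenarios, outDir,
                         methods = c("bayes", "chisq", "kruskal"),
                         criteria = c("quantile", "normal", "prob"),
                         backend = "gaussian", config = NULL,
                         extraMethods = NULL, force = FALSE) {
  if (is(scenarios, "ScenarioSpec")) scenarios <- list(scenarios)
  .prepareOutDir(outDir, force)
  nm <- names(scenarios)
  if (is.null(nm)) nm <- paste0("scenario", seq_along(scenarios))
  rows <- lapply(seq_along(scenarios), function(i) {
    sp <- scenarios[[i]]
    res <- runScenario(sp, methods = methods, criteria = criteria,
                       backend = backend, config = config,
                       extraMethods = extraMethods)
    cbind(scenario = nm[i], nLoci = sp@nLoci, cnvType = sp@cnvType,
          oddsRatio = sp@oddsRatio, res)
  })
  tab <- do.call(rbind, rows)
  .writeTsv(tab, file.path(outDir, "benchmark.tsv"))
  grid <- lapply(seq_along(scenarios), function(i) {
    sp <- scenarios[[i]]
    list(name = nm[i], nGroups = sp@nGroups, nLoci = sp@nLoci,
         nAssoc = sp@nAssoc, oddsRatio = sp@oddsRatio,
         freqRange = sp@freqRange, cnvType = sp@cnvType,
         nPerGroup = sp@nPerGroup, reps = sp@reps, alpha = sp@alpha,
         seed = sp@seed)
  })
  jsonlite::write_json(grid, file.path(outDir, "grid.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(tab)
}
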