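# Simulation-study harness: replicate simulate -> fit cycles over the
# scenario grid, tabulating bias and coverage for availability and density.

#' Deterministic replicate seed
#'
#' Pure function of (master seed, scenario id, replicate index), so grids
#' are resumable and reruns bit-identical.
#'
#' @param master Integer master seed.
#' @param id Scenario id string.
#' @param rep Replicate index.
#' @return Integer seed below 2^31.
#' @export
replicateSeed <- function(master, id, rep) {
  h <- sum(utf8ToInt(id) * (seq_len(nchar(id)) %% 31 + 1))
  as.integer((as.numeric(master) * 100003 + h * 7907 +
                as.numeric(rep) * 104729) %% 2147483629)
}

#' Evaluate one simulation scenario
#'
#' Runs \code{nReps} independent simulate-then-fit cycles and records,
#' per replicate, the posterior mean bias (posterior mean minus truth)
#' and 95\% credible-interval coverage for per-interval availability p_a
#' and density.  Density is tracked on two scales: \code{D}, the density
#' of birds present on the plot (from lambda * p_p; the scale on which
#' survey densities are reported), and \code{D_super}, the
#' superpopulation-scale density (from lambda alone, which is only weakly
#' identified with few visits).
#'
#' @param config A \linkS4class{ScenarioConfig}.
#' @param nReps Number of replicates (>= 2).
#' @param mcmc A \linkS4class{McmcSettings} for the fits.
#' @param seed Master seed; replicate seeds derive from it.
#' @param estimator \code{"mcmc"} fits the model; \code{"truth"} is a
#'   degenerate estimator that returns the simulated truth (bias 0,
#'   coverage 1), used to self-test the harness.
#' @return data.frame with columns scenario_id, rep, parameter, truth,
#'   post_mean, q2.5, q97.5, bias, covered, converged, failed.
#' @export
evaluateScenario <- function(config, nReps, mcmc = mcmcSettings(), seed = 1L,
                             estimator = c("mcmc", "truth")) {
  stopifnot(nReps >= 2)
  estimator <- match.arg(estimator)
  id <- scenarioId(config)
  p_a <- .resolvePa(config)
  B <- truncationRadius(config@binning)
  truths <- c(p_a = p_a,
              D = densityFromLambda(config@lambda * config@pPresence, B),
              D_super = densityFromLambda(config@lambda, B))
  out <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    rseed <- replicateSeed(seed, id, r)
    d <- simulateDataset(config, seed = rseed)
    row <- function(par, m, lo, hi, conv, failed = FALSE) {
      data.frame(scenario_id = id, rep = r, parameter = par,
                 truth = truths[[par]], post_mean = m, q2.5 = lo, q97.5 = hi,
                 bias = m - truths[[par]],
                 covered = as.integer(lo <= truths[[par]] &
                                        truths[[par]] <= hi),
                 converged = conv, failed = failed, stringsAsFactors = FALSE)
    }
    if (estimator == "truth") {
      out[[r]] <- do.call(rbind, lapply(names(truths), function(p)
        row(p, truths[[p]], truths[[p]], truths[[p]], TRUE)))
      next
    }
    fit <- tryCatch(
      suppressWarnings(fitStatic(d, mcmc = mcmc, seed = rseed)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      out[[r]] <- do.call(rbind, lapply(names(truths), function(p)
        row(p, NA_real_, NA_real_, NA_real_, FALSE, TRUE)))
      next
    }
    s <- posteriorSummary(fit)
    conv <- !any(grepl("non-convergent", fitFlags(fit)))
    g <- function(par) s[s$parameter == par, ]
    out[[r]] <- rbind(
      row("p_a", g("p_a")$mean, g("p_a")$q2.5, g("p_a")$q97.5, conv),
      row("D", g("D_pres")$mean, g("D_pres")$q2.5, g("D_pres")$q97.5, conv),
      row("D_super", g("D")$mean, g("D")$q2.5, g("D")$q97.5, conv))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the scenario grid
#'
#' @param grid Named list of \linkS4class{ScenarioConfig} (e.g. from
#'   \code{\link{scenarioGrid}}); names must be unique scenario ids.
#' @param nReps Replicates per scenario.
#' @param mcmc A \linkS4class{McmcSettings}.
#' @param seed Master seed.
#' @param estimator Passed to \code{\link{evaluateScenario}}.
#' @return data.frame of stacked replicate rows in stable grid order.
#' @export
runGrid <- function(grid, nReps, mcmc = mcmcSettings(), seed = 1L,
                    estimator = c("mcmc", "truth")) {
  stopifnot(length(grid) >= 1)
  ids <- vapply(grid, scenarioId, character(1))
  if (anyDuplicated(ids)) stop("duplicate scenario ids in grid")
  estimator <- match.arg(estimator)
  res <- lapply(grid, evaluateScenario, nReps = nReps, mcmc = mcmc,
                seed = seed, estimator = estimator)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-scenario bias quantile table
#'
#' Long-format tabular stand-in for the violin-plot summaries: for every
#' scenario and parameter, the 2.5/25/50/75/97.5\% bias quantiles, the
#' mean and relative bias, empirical coverage and the fraction of
#' replicates that converged.
#'
#' @param report Replicate-level data.frame from
#'   \code{\link{evaluateScenario}} or \code{\link{runGrid}}.
#' @param convergedOnly Drop non-converged replicates first.
#' @return data.frame with one row per (scenario, parameter, quantile)
#'   plus summary columns repeated within the group.
#' @export
summarizeViolin <- function(report, convergedOnly = FALSE) {
  stopifnot(nrow(report) > 0)
  report <- report[!report$failed, , drop = FALSE]
  if (convergedOnly) report <- report[report$converged, , drop = FALSE]
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  groups <- split(report, list(report$scenario_id, report$parameter),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    qs <- quantile(g$bias, probs, names = FALSE)
    data.frame(scenario_id = g$scenario_id[1], parameter = g$parameter[1],
               quantile = probs, value = qs,
               mean_bias = mean(g$bias),
               relative_bias = mean(g$bias) / g$truth[1],
               coverage = mean(g$covered),
               fraction_converged = mean(g$converged),
               n_reps = nrow(g), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$scenario_id, res$parameter, res$quantile), ]
}
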