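# Multi-year extension: dynamic abundance with a stationary AR(p) mean
# process and refuge random effects, fit with JAGS (latent annual counts
# sampled; observation layers collapsed to y ~ Bin(phi * p_d, N)).

.trendModelString <- function(p, nind, nrefuge, tauFixed = NULL,
                              init = "gamma") {
  gamma_def <- if (p == 1) "  gamma[1] <- gtot\n"
  else paste0("  gw ~ dbeta(1, 1)\n",
              "  gamma[1] <- gtot * gw\n",
              "  gamma[2] <- gtot * (1 - gw)\n")
  ar_terms <- paste(sprintf("gamma[%d] * N[k, t-%d]", seq_len(p), seq_len(p)),
                    collapse = " + ")
  ind_block <- if (nind > 0) paste0(
    "  for (i in 1:nind) {\n",
    "    dclass[i] ~ dcat(pic_d[1:nB])\n",
    "    tint[i] ~ dcat(pic_a[1:J])\n",
    "  }\n") else ""
  # with a single refuge the random effect is redundant with beta0
  refuge_block <- if (nrefuge == 1L) "  delta[1] <- 0\n  tau <- 1\n"
  else paste0(
    if (is.null(tauFixed)) "  tau ~ dgamma(0.001, 0.001)\n"
    else sprintf("  tau <- %.10g\n", tauFixed),
    "  for (r in 1:nrefuge) { delta[r] ~ dnorm(0, tau) }\n")
  paste0(
    "model {\n",
    "  # detection: intercept-only half-normal scale\n",
    "  rho0 ~ dnorm(0, 0.01)\n",
    "  sigma <- exp(rho0)\n",
    "  for (b in 1:nB) {\n",
    "    pi_d[b] <- exp(-mid[b]*mid[b] / (2*sigma*sigma)) * 2*mid[b]*w[b]/(B*B)\n",
    "    pic_d[b] <- pi_d[b] / p_d\n",
    "  }\n",
    "  p_d <- sum(pi_d[1:nB])\n",
    "  # availability: intercept-only logit, geometric removal cells\n",
    "  alpha0 ~ dnorm(0, 0.01)\n",
    "  logit(p_a) <- alpha0\n",
    "  for (j in 1:J) {\n",
    "    pi_a[j] <- p_a * pow(1 - p_a, j - 1)\n",
    "    pic_a[j] <- pi_a[j] / phi\n",
    "  }\n",
    "  phi <- sum(pi_a[1:J])\n",
    "  pdet <- phi * p_d\n",
    ind_block,
    "  # mean abundance: log link with refuge random effect\n",
    "  beta0 ~ dnorm(0, 0.01)\n",
    refuge_block,
    "  gtot ~ dbeta(1, 1)\n",
    gamma_def,
    "  for (k in 1:K) {\n",
    "    mu[k] <- exp(beta0 + delta[refuge[k]])\n",
    sprintf("    for (t in 1:%d) {\n", p),
    if (init == "gamma") "      lam0[k, t] ~ dgamma(a0, b0)\n"
    else                 "      lam0[k, t] <- mu[k]\n",
    "      N[k, t] ~ dpois(lam0[k, t])\n",
    "    }\n",
    sprintf("    for (t in %d:T) {\n", p + 1L),
    sprintf("      lam[k, t] <- %s + (1 - sum(gamma[1:%d])) * mu[k]\n",
            ar_terms, p),
    "      N[k, t] ~ dpois(lam[k, t])\n",
    "    }\n",
    "    for (t in 1:T) { y[k, t] ~ dbin(pdet, N[k, t]) }\n",
    "  }\n",
    "  for (t in 1:T) { Ntot[t] <- sum(N[1:K, t]) }\n",
    "}\n")
}

#' One-step AR mean
#'
#' The convex autoregression/regression mixture driving annual mean
#' abundance: \code{lambda_t = sum_i gamma_i N_[t-i] +
#' (1 - sum_i gamma_i) mu}, with lag i reading i years back.
#'
#' @param gamma AR coefficients, each in [0,1) with sum < 1.
#' @param Nprev Abundance history, \code{Nprev[i]} = N at lag i.
#' @param mu Stationary regression mean exp(X beta).
#' @return The Poisson mean for the next year.
#' @export
arMean <- function(gamma, Nprev, mu) {
  stopifnot(length(gamma) == length(Nprev), all(gamma >= 0), sum(gamma) < 1)
  sum(gamma * Nprev) + (1 - sum(gamma)) * mu
}

#' Fit the multi-year AR(p) trend model
#'
#' Annual abundance N_kt ~ Poisson(lambda_kt) evolves by the stationary
#' convex mixture of lagged abundances and the log-linear regression mean
#' exp(beta0 + delta_refuge); the observation layer per year is the
#' single-season hybrid model (availability and perceptibility collapse
#' to one thinning, y ~ Binomial(phi p_d, N)).  Initial years use
#' configurable Gamma means.  Fit by MCMC in JAGS.
#'
#' @param dataset A multi-year \linkS4class{PointCountDataset} with one
#'   visit per year.
#' @param spec A \linkS4class{TrendModelSpec} (AR order, initial-year
#'   hyperparameters).
#' @param mcmc A \linkS4class{McmcSettings}.
#' @param seed Integer seed.
#' @param tauFixed Optionally fix the refuge random-effect precision
#'   (large values force the effects to zero).
#' @return A \linkS4class{TrendPosterior}.
#' @export
fitTrend <- function(dataset, spec = trendModelSpec(), mcmc = mcmcSettings(),
                     seed = 1L, tauFixed = NULL) {
  stopifnot(is(dataset, "PointCountDataset"))
  validObject(dataset)
  if (length(dataset@years) < 2L)
    stop("single-year dataset: use fitStatic() for single-season data")
  if (dataset@nVisits != 1L)
    stop("the trend model indexes annual occasions; supply one visit per year")
  seed <- as.integer(seed)
  p <- spec@order
  years <- sort(dataset@years)
  TT <- length(years)
  pts <- dataset@points[order(dataset@points$point_id), , drop = FALSE]
  K <- nrow(pts)
  counts <- observedCounts(dataset)
  y <- matrix(0L, K, TT)
  ki <- match(counts$point_id, pts$point_id)
  ti <- match(counts$year, years)
  y[cbind(ki, ti)] <- counts$y
  det <- dataset@detections
  nind <- nrow(det)
  refuges <- sort(unique(pts$refuge))
  dat <- list(y = y, K = K, T = TT,
              refuge = match(pts$refuge, refuges),
              nrefuge = length(refuges),
              mid = binMidpoints(dataset@binning),
              w = binWidths(dataset@binning),
              B = truncationRadius(dataset@binning),
              nB = nBins(dataset@binning), J = nIntervals(dataset@removal),
              a0 = spec@initShapeRate[1], b0 = spec@initShapeRate[2])
  if (nind > 0) {
    dat$dclass <- as.integer(det$distance_class)
    dat$tint <- as.integer(det$time_interval)
    dat$nind <- nind
  }
  modelStr <- .trendModelString(p, nind, length(refuges), tauFixed,
                                init = spec@init)

  mkInits <- function(chain) {
    set.seed(.pointSeed(seed, 2000L + chain))
    Ninit <- y + 2L
    ii <- list(N = Ninit, gtot = runif(1, 0.2, 0.8),
               beta0 = log(max(mean(y), 0.2) / 0.2) + rnorm(1, 0, 0.2),
               alpha0 = rnorm(1, 1, 0.3), rho0 = log(55) + rnorm(1, 0, 0.1),
               .RNG.name = "base::Mersenne-Twister",
               .RNG.seed = .pointSeed(seed, 3000L + chain))
    if (spec@init == "gamma")
      ii$lam0 <- matrix(pmax(rowMeans(y) * 4 + 1, 1), K, p)
    if (length(refuges) > 1) {
      ii$delta <- rep(0, length(refuges))
      if (is.null(tauFixed)) ii$tau <- 1
    }
    if (p == 2) ii$gw <- 0.5
    ii
  }
  inits <- lapply(seq_len(mcmc@chains), mkInits)

  jm <- rjags::jags.model(textConnection(modelStr), data = dat,
                          inits = inits, n.chains = mcmc@chains,
                          n.adapt = mcmc@adaptation, quiet = TRUE)
  if (mcmc@burnIn > 0) stats::update(jm, mcmc@burnIn, progress.bar = "none")
  monitors <- c("gamma", "gtot", "beta0", "delta", "tau", "alpha0", "p_a",
                "phi", "sigma", "p_d", "Ntot")
  samp <- rjags::coda.samples(jm, monitors,
                              n.iter = mcmc@iterations - mcmc@burnIn,
                              thin = mcmc@thin, progress.bar = "none")
  chains <- lapply(samp, as.matrix)
  names(chains) <- paste0("chain", seq_along(chains))
  summ <- .summarizeDraws(chains)

  flags <- character(0)
  core <- c(paste0("gamma[", seq_len(p), "]"), "beta0", "p_a", "sigma")
  bad <- summ$parameter[summ$parameter %in% core & !is.na(summ$rhat) &
                          summ$rhat > 1.1]
  if (length(bad)) {
    flags <- c(flags, paste0("non-convergent: Rhat > 1.1 for ",
                             paste(bad, collapse = ", ")))
    warning("chains may not have converged (Rhat > 1.1 for ",
            paste(bad, collapse = ", "), ")")
  }
  if (nind == 0L) flags <- c(flags, "prior-dominated: zero detections")

  all <- do.call(rbind, chains)
  B <- truncationRadius(dataset@binning)
  annual <- do.call(rbind, lapply(seq_len(TT), function(t) {
    nt <- all[, paste0("Ntot[", t, "]")] / K
    Dt <- densityFromLambda(nt, B)
    qs <- quantile(Dt, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(year = years[t], meanAbundance = mean(nt), density = mean(Dt),
               density_q2.5 = qs[1], density_q50 = qs[2],
               density_q97.5 = qs[3], stringsAsFactors = FALSE)
  }))
  new("TrendPosterior", summary = summ, draws = chains, annual = annual,
      spec = spec, settings = mcmc, seed = seed, flags = flags)
}

#' Percent annual change of a trajectory
#'
#' Log-linear convention: the least-squares slope b of log(abundance) on
#' year, reported as 100 (exp(b) - 1) percent per year.  The
#' \code{"per_step"} alternative is the geometric mean of year-over-year
#' growth rates (identical for exactly geometric trajectories).
#'
#' @param traj Positive abundance trajectory (one value per year).
#' @param method \code{"loglinear"} (default) or \code{"per_step"}.
#' @return Percent change per year.
#' @examples
#' percentChangeFromTrajectory(c(10, 11, 12.1, 13.31))  # +10 %/yr
#' @export
percentChangeFromTrajectory <- function(traj,
                                        method = c("loglinear", "per_step")) {
  method <- match.arg(method)
  if (any(traj <= 0)) stop("trajectory must be strictly positive")
  if (length(traj) < 2) stop("need at least 2 years")
  b <- if (method == "loglinear") {
    yr <- seq_along(traj)
    unname(coef(lm(log(traj) ~ yr))[2])
  } else mean(diff(log(traj)))
  100 * (exp(b) - 1)
}

#' Posterior percent annual change from a trend fit
#'
#' Applies \code{\link{percentChangeFromTrajectory}} to each posterior
#' draw of the annual mean-abundance trajectory and summarizes.  Draws
#' with any non-positive annual mean are skipped and counted.
#'
#' @param trend A \linkS4class{TrendPosterior}.
#' @param method Passed to \code{\link{percentChangeFromTrajectory}}.
#' @return List with \code{mean}, \code{q2.5}, \code{q50}, \code{q97.5},
#'   \code{draws} and \code{nSkipped}.
#' @export
percentChange <- function(trend, method = c("loglinear", "per_step")) {
  stopifnot(is(trend, "TrendPosterior"))
  method <- match.arg(method)
  all <- do.call(rbind, trend@draws)
  cols <- grep("^Ntot\\[", colnames(all), value = TRUE)
  cols <- cols[order(as.integer(gsub("\\D", "", cols)))]
  traj <- all[, cols, drop = FALSE]
  ok <- rowSums(traj <= 0) == 0
  vals <- apply(traj[ok, , drop = FALSE], 1, percentChangeFromTrajectory,
                method = method)
  qs <- quantile(vals, c(0.025, 0.5, 0.975), names = FALSE)
  nSkipped <- sum(!ok)
  if (nSkipped > 0)
    message(nSkipped, " draw(s) skipped (non-positive annual mean)")
  list(mean = mean(vals), q2.5 = qs[1], q50 = qs[2], q97.5 = qs[3],
       draws = vals, nSkipped = nSkipped)
}
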