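# Single-season fit of the hybrid distance-sampling x time-removal
# hierarchical model.  The latent count layers are marginalized exactly
# (Poisson thinning), leaving a 4-parameter posterior over
# (lambda, p_p, p_a, sigma) sampled by adaptive random-walk Metropolis.

.PARAMS <- c("lambda", "p_p", "p_a", "sigma", "phi", "p_d", "D", "D_pres")

# log-posterior on the unconstrained scale
# theta = (log lambda, logit p_p, logit p_a, log sigma)
.makeLogPost <- function(y, wy, ndist, ntime, mid, w, B, priors, lgam) {
  lo <- priors@logSigmaRange[1]; hi <- priors@logSigmaRange[2]
  function(theta) {
    lsig <- theta[4]
    if (lsig < lo || lsig > hi) return(-Inf)
    lambda <- exp(theta[1])
    p_p <- stats::plogis(theta[2])
    p_a <- stats::plogis(theta[3])
    # Gamma(0.1, 0.1) prior mass beyond 1e6 is nil; bounding lambda keeps
    # the Poisson truncation point (and its work buffer) finite
    if (!is.finite(lambda) || lambda <= 0 || lambda > 1e6) return(-Inf)
    ll <- staticLogLik(y, wy, ndist, ntime, mid, w, B, lambda, p_p, p_a,
                       exp(lsig), lgam)
    if (!is.finite(ll)) return(-Inf)
    # priors with change-of-variable Jacobians
    lp <- stats::dgamma(lambda, priors@lambdaShapeRate[1],
                        priors@lambdaShapeRate[2], log = TRUE) + theta[1] +
      stats::dbeta(p_p, priors@ppShape[1], priors@ppShape[2], log = TRUE) +
      log(p_p) + log1p(-p_p) +
      stats::dbeta(p_a, priors@paShape[1], priors@paShape[2], log = TRUE) +
      log(p_a) + log1p(-p_a)
    ll + lp
  }
}

# Adaptive Metropolis: joint normal proposal; scale and covariance adapted
# during burn-in only, frozen afterwards so the retained chain targets the
# exact posterior.
.runChain <- function(logPost, init, iterations, burnIn, thin, adaptEvery = 50) {
  d <- length(init)
  theta <- init
  lp <- logPost(theta)
  if (!is.finite(lp)) stop("initial values have zero posterior density")
  scale <- 2.38 / sqrt(d)
  L <- diag(0.1, d)
  hist <- matrix(NA_real_, burnIn, d)
  keep <- matrix(NA_real_, length(seq(burnIn + 1L, iterations, by = thin)), d)
  ki <- 0L
  accWin <- 0L
  for (i in seq_len(iterations)) {
    prop <- theta + scale * as.vector(L %*% rnorm(d))
    lpp <- logPost(prop)
    if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
      theta <- prop; lp <- lpp; accWin <- accWin + 1L
    }
    if (i <= burnIn) {
      hist[i, ] <- theta
      if (i %% adaptEvery == 0L) {
        acc <- accWin / adaptEvery
        scale <- scale * exp(0.66 * (acc - 0.3))
        accWin <- 0L
        if (i >= 200L) {
          S <- stats::cov(hist[seq_len(i), , drop = FALSE]) + diag(1e-8, d)
          ch <- tryCatch(chol(S), error = function(e) NULL)
          if (!is.null(ch)) L <- t(ch)
        }
      }
    } else if ((i - burnIn) %% thin == 0L) {
      ki <- ki + 1L
      keep[ki, ] <- theta
    }
  }
  keep[seq_len(ki), , drop = FALSE]
}

.summarizeDraws <- function(chains) {
  params <- colnames(chains[[1]])
  all <- do.call(rbind, chains)
  rows <- lapply(params, function(p) {
    x <- all[, p]
    qs <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    rh <- if (length(chains) >= 2)
      gelmanRubin(lapply(chains, function(ch) ch[, p])) else NA_real_
    ne <- tryCatch(
      sum(vapply(chains, function(ch) coda::effectiveSize(ch[, p]),
                 numeric(1))),
      error = function(e) NA_real_)
    data.frame(parameter = p, mean = mean(x), sd = sd(x), q2.5 = qs[1],
               q50 = qs[2], q97.5 = qs[3], rhat = rh, n_eff = ne,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit the single-season hybrid model
#'
#' Joint posterior over mean superpopulation size lambda, presence
#' probability p_p, per-interval availability p_a and half-normal scale
#' sigma, with derived overall availability phi, perceptibility p_d and
#' density D (birds/km^2).  The likelihood combines (i) conditional
#' multinomial distance-class terms, (ii) conditional time-interval
#' removal terms, and (iii) the count hierarchy
#' y <- N_avail <- N_pres <- N_super, with the latent counts summed out
#' exactly.
#'
#' @param dataset A single-year \linkS4class{PointCountDataset}.
#' @param priors A \linkS4class{PriorSpec}.
#' @param mcmc A \linkS4class{McmcSettings}.
#' @param seed Integer seed (one per fit; chains derive sub-seeds).
#' @return A \linkS4class{PosteriorSummary}.  Flags record zero-detection
#'   (prior-dominated) fits, weak identifiability of p_p with single-visit
#'   data, and non-convergence (any Rhat > 1.1, also raised as a warning).
#' @examples
#' \donttest{
#' d <- simulateDataset(scenarioConfig(nPoints = 100, nVisits = 3), seed = 1)
#' fit <- fitStatic(d, seed = 1)
#' posteriorSummary(fit)
#' }
#' @export
fitStatic <- function(dataset, priors = priorSpec(), mcmc = mcmcSettings(),
                      seed = 1L) {
  stopifnot(is(dataset, "PointCountDataset"))
  validObject(dataset)
  if (length(dataset@years) > 1L)
    stop("dataset spans multiple years; use fitTrend() for multi-year data")
  seed <- as.integer(seed)
  counts <- observedCounts(dataset)
  K <- nrow(dataset@points); TT <- dataset@nVisits
  y <- matrix(counts$y[order(counts$point_id, counts$visit)], nrow = K,
              ncol = TT, byrow = TRUE)
  storage.mode(y) <- "integer"
  det <- dataset@detections
  nb <- nBins(dataset@binning); J <- nIntervals(dataset@removal)
  ndist <- tabulate(det$distance_class, nb)
  ntime <- tabulate(det$time_interval, J)
  mid <- binMidpoints(dataset@binning)
  w <- binWidths(dataset@binning)
  B <- truncationRadius(dataset@binning)
  lgam <- lgamma(seq_len(8192L))  # lgam[i] = lgamma(i), index i = n + 1

  flags <- character(0)
  if (nrow(det) == 0L) flags <- c(flags, "prior-dominated: zero detections")
  if (TT == 1L)
    flags <- c(flags,
               "weakly-identified: with a single visit, lambda and p_p enter the count likelihood only through their product")

  # collapse duplicate count rows (exchangeable points): the likelihood
  # only needs unique rows and their multiplicities
  key <- do.call(paste, c(as.data.frame(y), sep = ","))
  idx <- !duplicated(key)
  uy <- y[idx, , drop = FALSE]
  wy <- as.integer(table(key)[key[idx]])

  logPost <- .makeLogPost(uy, wy, ndist, ntime, mid, w, B, priors, lgam)

  # data-driven center for initial values, jittered per chain
  ybar <- mean(y)
  lam0 <- max(ybar / 0.2, 0.5)
  chains <- vector("list", mcmc@chains)
  for (c in seq_len(mcmc@chains)) {
    set.seed(.pointSeed(seed, 1000L + c))
    init <- c(log(lam0), 0, 0, log(B / 3)) + rnorm(4, 0, 0.3)
    init[4] <- min(max(init[4], priors@logSigmaRange[1] + 0.1),
                   priors@logSigmaRange[2] - 0.1)
    raw <- .runChain(logPost, init, mcmc@iterations, mcmc@burnIn, mcmc@thin)
    lambda <- exp(raw[, 1])
    p_p <- stats::plogis(raw[, 2])
    p_a <- stats::plogis(raw[, 3])
    sigma <- exp(raw[, 4])
    phi <- 1 - (1 - p_a)^J
    p_d <- colSums(exp(-outer(mid^2, 1 / (2 * sigma^2))) * (2 * mid * w / B^2))
    D <- densityFromLambda(lambda, B)
    chains[[c]] <- cbind(lambda = lambda, p_p = p_p, p_a = p_a,
                         sigma = sigma, phi = phi, p_d = p_d, D = D,
                         D_pres = densityFromLambda(lambda * p_p, B))
  }
  names(chains) <- paste0("chain", seq_along(chains))
  summ <- .summarizeDraws(chains)
  bad <- summ$parameter[!is.na(summ$rhat) & summ$rhat > 1.1]
  if (length(bad)) {
    flags <- c(flags, paste0("non-convergent: Rhat > 1.1 for ",
                             paste(bad, collapse = ", ")))
    warning("chains may not have converged (Rhat > 1.1 for ",
            paste(bad, collapse = ", "), ")")
  }
  new("PosteriorSummary", summary = summ, draws = chains, settings = mcmc,
      seed = seed, flags = flags)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF from between- and within-chain variances:
#' \code{Rhat = sqrt(((n-1)/n W + (1 + 1/m) B_n) / W)} for m chains of
#' length n, where W is the mean within-chain variance and B_n the
#' variance of the chain means.  Approaches 1 as chains agree and
#' lengthen.
#'
#' @param chains List of >= 2 equal-length numeric vectors (one per
#'   chain), or a matrix with one chain per column.
#' @return The PSRF (a scalar >= ~sqrt((n-1)/n)).
#' @export
gelmanRubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop("diagnostic unavailable: need at least 2 chains")
  n <- unique(vapply(chains, length, integer(1)))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 10) stop("chains must have length >= 10")
  W <- mean(vapply(chains, var, numeric(1)))
  Bn <- var(vapply(chains, mean, numeric(1)))  # = B/n in the usual notation
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + (1 + 1 / m) * Bn) / W)
}

#' Density from mean abundance
#'
#' Converts mean superpopulation size per point to birds/km^2 given the
#' truncation radius: \code{D = lambda / (pi B^2 1e-6)}.
#'
#' @param lambda Mean abundance per point (vectorized).
#' @param B Truncation radius in meters.
#' @return Density in birds/km^2.
#' @export
densityFromLambda <- function(lambda, B) {
  lambda / (pi * (B / 1000)^2)
}

#' Posterior density derived from a fitted model
#'
#' Maps the posterior draws of lambda through the point-area conversion
#' and summarizes the resulting density posterior like any other
#' parameter.
#'
#' @param posterior A \linkS4class{PosteriorSummary} with lambda draws.
#' @param binning The \linkS4class{DistanceBinning} defining the point
#'   area (its truncation radius).
#' @return List with \code{draws} (all chains pooled) and \code{summary}
#'   (one-row data.frame).
#' @export
deriveDensity <- function(posterior, binning = distanceBinning()) {
  stopifnot(is(posterior, "PosteriorSummary"))
  lam <- unlist(lapply(posterior@draws, function(ch) ch[, "lambda"]),
                use.names = FALSE)
  D <- densityFromLambda(lam, truncationRadius(binning))
  qs <- quantile(D, c(0.025, 0.5, 0.975), names = FALSE)
  list(draws = D,
       summary = data.frame(parameter = "D", mean = mean(D), sd = sd(D),
                            q2.5 = qs[1], q50 = qs[2], q97.5 = qs[3],
                            stringsAsFactors = FALSE))
}
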