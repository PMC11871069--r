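#' @import methods
#' @importFrom stats dpois dbinom rbinom rpois rmultinom quantile sd var
#'   rgamma rbeta runif rnorm median qnorm setNames coef lm aggregate
#' @importFrom utils read.csv write.csv head
#' @useDynLib distrem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Radial distance binning for point counts
#'
#' Distance classes into which detections are binned, out to a truncation
#' radius \code{B} (the last edge).  The default reproduces the survey
#' protocol bins 0--25, >25--50, >50--100 and >100--150 m.
#'
#' @slot edges Numeric vector of strictly increasing bin edges in meters,
#'   starting at 0; the last edge is the truncation radius.
#' @export
setClass("DistanceBinning", representation(edges = "numeric"))

setValidity("DistanceBinning", function(object) {
  e <- object@edges
  if (length(e) < 2) return("need at least two edges")
  if (anyNA(e)) return("edges must not contain NA")
  if (e[1] != 0) return("first edge must be 0")
  if (any(diff(e) <= 0)) return("edges must be strictly increasing")
  TRUE
})

#' Construct a distance binning
#'
#' @param edges Bin edges in meters; strictly increasing, starting at 0.
#'   The last edge is the truncation radius.
#' @return A \linkS4class{DistanceBinning}.
#' @examples
#' b <- distanceBinning()          # 0-25, 25-50, 50-100, 100-150 m
#' binMidpoints(b)
#' @export
distanceBinning <- function(edges = c(0, 25, 50, 100, 150)) {
  new("DistanceBinning", edges = as.numeric(edges))
}

#' Time-removal scheme
#'
#' Number of removal intervals within a count and their nominal minute
#' labels.  The removal model treats intervals as \code{J} exchangeable
#' periods; the labels are carried for bookkeeping only.
#'
#' @slot J Integer, number of removal intervals (>= 1).
#' @slot labels Character labels for the intervals.
#' @export
setClass("TimeRemovalScheme",
         representation(J = "integer", labels = "character"))

setValidity("TimeRemovalScheme", function(object) {
  if (object@J < 1L) return("J must be >= 1")
  if (length(object@labels) != object@J)
    return("labels must have length J")
  TRUE
})

#' Construct a time-removal scheme
#'
#' @param J Number of removal intervals.
#' @param labels Interval labels; defaults to the 10-min protocol
#'   0--3, >3--5, >5--10 min when \code{J = 3}.
#' @return A \linkS4class{TimeRemovalScheme}.
#' @export
timeRemovalScheme <- function(J = 3L, labels = NULL) {
  J <- as.integer(J)
  if (is.null(labels)) {
    labels <- if (J == 3L) c("0-3 min", ">3-5 min", ">5-10 min")
              else paste0("interval ", seq_len(J))
  }
  new("TimeRemovalScheme", J = J, labels = labels)
}

#' Simulation scenario configuration
#'
#' All knobs of the synthetic-data generator.  Defaults are the simulation
#' study conditions: mean superpopulation \code{lambda = 5} per point,
#' half-normal scale \code{sigma = 55} m, 150 m truncation with four
#' distance bins, and three removal intervals.
#'
#' @slot lambda Mean superpopulation size per point.
#' @slot pPresence Probability a superpopulation member is on the plot
#'   during a visit.
#' @slot availability Availability level: per-interval \code{p_a} or
#'   overall \code{phi}, see \code{availabilityInterpretation}.
#' @slot availabilityInterpretation Either \code{"per_interval"} (default)
#'   or \code{"overall"}.
#' @slot nPoints Number of survey points K.
#' @slot nVisits Number of within-season visits T.
#' @slot sigma Half-normal detection scale in meters.
#' @slot binning A \linkS4class{DistanceBinning}.
#' @slot removal A \linkS4class{TimeRemovalScheme}.
#' @export
setClass("ScenarioConfig",
         representation(lambda = "numeric", pPresence = "numeric",
                        availability = "numeric",
                        availabilityInterpretation = "character",
                        nPoints = "integer", nVisits = "integer",
                        sigma = "numeric", binning = "DistanceBinning",
                        removal = "TimeRemovalScheme"))

setValidity("ScenarioConfig", function(object) {
  if (object@lambda <= 0) return("lambda must be > 0")
  if (object@pPresence <= 0 || object@pPresence >= 1)
    return("pPresence must be in (0,1)")
  if (object@availability <= 0 || object@availability >= 1)
    return("availability must be in (0,1)")
  if (!object@availabilityInterpretation %in% c("per_interval", "overall"))
    return("availabilityInterpretation must be 'per_interval' or 'overall'")
  if (object@nPoints < 1L) return("nPoints must be >= 1")
  if (object@nVisits < 1L) return("nVisits must be >= 1")
  if (object@sigma <= 0) return("sigma must be > 0")
  TRUE
})

#' Construct a scenario configuration
#'
#' @param lambda Mean superpopulation per point (default 5).
#' @param pPresence Presence probability (default 0.8).
#' @param availability Availability level (default 0.8).
#' @param availabilityInterpretation \code{"per_interval"} (the level is
#'   p_a, the default) or \code{"overall"} (the level is phi).
#' @param nPoints Number of points K (default 50).
#' @param nVisits Number of visits T (default 1).
#' @param sigma Half-normal scale in meters (default 55).
#' @param binning Distance binning (default four-bin 150 m scheme).
#' @param removal Time-removal scheme (default J = 3).
#' @return A \linkS4class{ScenarioConfig}.
#' @export
scenarioConfig <- function(lambda = 5, pPresence = 0.8, availability = 0.8,
                           availabilityInterpretation = "per_interval",
                           nPoints = 50L, nVisits = 1L, sigma = 55,
                           binning = distanceBinning(),
                           removal = timeRemovalScheme()) {
  new("ScenarioConfig", lambda = lambda, pPresence = pPresence,
      availability = availability,
      availabilityInterpretation = availabilityInterpretation,
      nPoints = as.integer(nPoints), nVisits = as.integer(nVisits),
      sigma = sigma, binning = binning, removal = removal)
}

#' Point-count dataset
#'
#' One detection per row plus the roster of surveyed point-year-visits
#' (needed so that zero-count surveys are represented).  Single-season
#' datasets have one year; multi-year datasets are consumed by
#' \code{\link{fitTrend}}.
#'
#' @slot detections data.frame with columns refuge, point_id, year, visit,
#'   species, distance_class, time_interval (one detected individual per
#'   row).
#' @slot points data.frame with columns point_id, refuge.
#' @slot years Integer vector of surveyed years.
#' @slot nVisits Visits per point per year.
#' @slot binning A \linkS4class{DistanceBinning}.
#' @slot removal A \linkS4class{TimeRemovalScheme}.
#' @export
setClass("PointCountDataset",
         representation(detections = "data.frame", points = "data.frame",
                        years = "integer", nVisits = "integer",
                        binning = "DistanceBinning",
                        removal = "TimeRemovalScheme"))

.DET_COLS <- c("refuge", "point_id", "year", "visit", "species",
               "distance_class", "time_interval")

setValidity("PointCountDataset", function(object) {
  d <- object@detections
  if (!all(.DET_COLS %in% names(d)))
    return(paste("detections must have columns:",
                 paste(.DET_COLS, collapse = ", ")))
  nb <- nBins(object@binning)
  J <- nIntervals(object@removal)
  if (nrow(d)) {
    if (any(d$distance_class < 1 | d$distance_class > nb))
      return(sprintf("distance_class out of range 1..%d", nb))
    if (any(d$time_interval < 1 | d$time_interval > J))
      return(sprintf("time_interval out of range 1..%d", J))
    if (!all(d$point_id %in% object@points$point_id))
      return("detections reference unknown point_id")
    if (!all(d$year %in% object@years))
      return("detections reference unknown year")
    if (any(d$visit < 1 | d$visit > object@nVisits))
      return("visit out of range")
  }
  TRUE
})

#' Simulated point-count dataset
#'
#' A \linkS4class{PointCountDataset} that also carries the latent states
#' of the generating hierarchy, so that every inference stage can be
#' checked against truth.
#'
#' @slot latents data.frame keyed by (point_id, year, visit) with columns
#'   N_super, N_pres, N_avail, y.
#' @slot config The generating \linkS4class{ScenarioConfig}.
#' @slot seed Integer master seed used.
#' @export
setClass("SimulatedDataset", contains = "PointCountDataset",
         representation(latents = "data.frame", config = "ScenarioConfig",
                        seed = "integer"))

setValidity("SimulatedDataset", function(object) {
  l <- object@latents
  need <- c("point_id", "year", "visit", "N_super", "N_pres", "N_avail", "y")
  if (!all(need %in% names(l)))
    return(paste("latents must have columns:", paste(need, collapse = ", ")))
  bad <- with(l, y > N_avail | N_avail > N_pres | N_pres > N_super |
                 y < 0 | N_super < 0)
  if (any(bad)) return("latent ordering y <= N_avail <= N_pres <= N_super violated")
  TRUE
})

#' Prior specification for the single-season model
#'
#' Vague defaults: p_a, p_p ~ Beta(1,1); log(sigma) ~ Uniform(0,10);
#' lambda ~ Gamma(0.1, 0.1).
#'
#' @slot paShape Beta shape parameters (length 2) for p_a.
#' @slot ppShape Beta shape parameters (length 2) for p_p.
#' @slot logSigmaRange Uniform bounds for log(sigma).
#' @slot lambdaShapeRate Gamma shape and rate for lambda.
#' @export
setClass("PriorSpec",
         representation(paShape = "numeric", ppShape = "numeric",
                        logSigmaRange = "numeric", lambdaShapeRate = "numeric"))

setValidity("PriorSpec", function(object) {
  if (any(c(object@paShape, object@ppShape, object@lambdaShapeRate) <= 0))
    return("hyperparameters must be strictly positive")
  if (length(object@logSigmaRange) != 2 || diff(object@logSigmaRange) <= 0)
    return("logSigmaRange must be an increasing pair")
  TRUE
})

#' Construct a prior specification
#'
#' @param paShape,ppShape Beta hyperparameters for p_a and p_p.
#' @param logSigmaRange Uniform bounds for log(sigma).
#' @param lambdaShapeRate Gamma (shape, rate) for lambda.
#' @return A \linkS4class{PriorSpec}.
#' @export
priorSpec <- function(paShape = c(1, 1), ppShape = c(1, 1),
                      logSigmaRange = c(0, 10),
                      lambdaShapeRate = c(0.1, 0.1)) {
  new("PriorSpec", paShape = paShape, ppShape = ppShape,
      logSigmaRange = logSigmaRange, lambdaShapeRate = lambdaShapeRate)
}

#' MCMC settings
#'
#' The \code{"test"} profile (3 chains x 4000 iterations, 1000 burn-in,
#' thin 2) is sized for desk-scale work; the \code{"paper"} profile uses
#' the original long-run settings (3 chains x 650,000 iterations, 50,000
#' burn-in, 5,000 adaptation, thin 20).
#'
#' @slot chains,iterations,burnIn,adaptation,thin Integers.
#' @export
setClass("McmcSettings",
         representation(chains = "integer", iterations = "integer",
                        burnIn = "integer", adaptation = "integer",
                        thin = "integer"))

setValidity("McmcSettings", function(object) {
  if (object@iterations <= object@burnIn) return("iterations must exceed burnIn")
  if (object@burnIn < 0) return("burnIn must be >= 0")
  if (object@thin < 1) return("thin must be >= 1")
  if (object@chains < 2) return("need >= 2 chains for convergence diagnostics")
  TRUE
})

#' Construct MCMC settings
#'
#' @param profile \code{"test"} (default) or \code{"paper"}; individual
#'   arguments override the profile.
#' @param chains,iterations,burnIn,adaptation,thin Overrides.
#' @return A \linkS4class{McmcSettings}.
#' @export
mcmcSettings <- function(profile = c("test", "paper"), chains = NULL,
                         iterations = NULL, burnIn = NULL,
                         adaptation = NULL, thin = NULL) {
  profile <- match.arg(profile)
  def <- if (profile == "test")
    list(chains = 3L, iterations = 4000L, burnIn = 1000L,
         adaptation = 500L, thin = 2L)
  else
    list(chains = 3L, iterations = 650000L, burnIn = 50000L,
         adaptation = 5000L, thin = 20L)
  pick <- function(x, d) if (is.null(x)) d else as.integer(x)
  new("McmcSettings",
      chains = pick(chains, def$chains),
      iterations = pick(iterations, def$iterations),
      burnIn = pick(burnIn, def$burnIn),
      adaptation = pick(adaptation, def$adaptation),
      thin = pick(thin, def$thin))
}

#' Posterior summary of a single-season fit
#'
#' @slot summary data.frame: one row per parameter with mean, sd,
#'   quantiles (2.5/50/97.5\%), Rhat and effective draws.
#' @slot draws Named list of post-burn-in draw matrices, one per chain
#'   (columns = parameters).
#' @slot settings The \linkS4class{McmcSettings} used.
#' @slot seed Integer seed.
#' @slot flags Character vector of warnings raised during fitting
#'   (e.g. non-convergence, weak identifiability, prior-dominated).
#' @export
setClass("PosteriorSummary",
         representation(summary = "data.frame", draws = "list",
                        settings = "McmcSettings", seed = "integer",
                        flags = "character"))

#' Trend model specification
#'
#' @slot order AR order p (1 or 2).
#' @slot initShapeRate Gamma hyperparameters for the initial-year
#'   abundance means (used when \code{init = "gamma"}).
#' @slot init Initial-year treatment: \code{"gamma"} gives every point a
#'   free Gamma-distributed year-1 mean; \code{"stationary"} starts the
#'   process at its stationary regression mean exp(beta0 + delta).
#' @export
setClass("TrendModelSpec",
         representation(order = "integer", initShapeRate = "numeric",
                        init = "character"))

#' Construct a trend model specification
#'
#' @param order AR order p in \{1, 2\}.
#' @param initShapeRate Gamma (shape, rate) for the initial-year means
#'   (default \code{c(0.1, 0.1)}).
#' @param init \code{"gamma"} (default; free per-point initial means) or
#'   \code{"stationary"} (initial years start at the stationary mean;
#'   the appropriate choice when the population is believed to be at its
#'   long-run level when surveys begin, and the setting used in the
#'   package's parameter-recovery experiments).
#' @return A \linkS4class{TrendModelSpec}.
#' @export
trendModelSpec <- function(order = 1L, initShapeRate = c(0.1, 0.1),
                           init = c("gamma", "stationary")) {
  order <- as.integer(order)
  init <- match.arg(init)
  stopifnot(order >= 1L, order <= 2L, all(initShapeRate > 0))
  new("TrendModelSpec", order = order, initShapeRate = initShapeRate,
      init = init)
}

#' Posterior summary of a multi-year trend fit
#'
#' @slot summary data.frame as in \linkS4class{PosteriorSummary}.
#' @slot draws Named list of per-chain draw matrices.
#' @slot annual data.frame of annual mean-abundance and density summaries.
#' @slot spec The \linkS4class{TrendModelSpec} used.
#' @slot settings,seed,flags As in \linkS4class{PosteriorSummary}.
#' @export
setClass("TrendPosterior",
         representation(summary = "data.frame", draws = "list",
                        annual = "data.frame", spec = "TrendModelSpec",
                        settings = "McmcSettings", seed = "integer",
                        flags = "character"))

#' Pilot survey summary for sample-size calculations
#'
#' @slot n0 Total detections in the pilot survey.
#' @slot k0 Number of points surveyed.
#' @slot cvObs Observed coefficient of variation of the density estimate.
#' @slot densityHat Optional density estimate (NA if unknown).
#' @export
setClass("PilotSummary",
         representation(n0 = "numeric", k0 = "numeric", cvObs = "numeric",
                        densityHat = "numeric"))

setValidity("PilotSummary", function(object) {
  if (object@n0 < 0 || object@n0 != round(object@n0))
    return("n0 must be a non-negative integer count")
  if (object@k0 < 1) return("k0 must be >= 1")
  if (object@cvObs <= 0) return("cvObs must be > 0")
  TRUE
})

#' Construct a pilot summary
#'
#' @param n0 Total detections.
#' @param k0 Points surveyed.
#' @param cvObs Observed CV of the density estimate.
#' @param densityHat Optional density estimate.
#' @return A \linkS4class{PilotSummary}.
#' @examples
#' pilotSummary(n0 = 668, k0 = 91, cvObs = 0.2)
#' @export
pilotSummary <- function(n0, k0, cvObs, densityHat = NA_real_) {
  new("PilotSummary", n0 = as.numeric(n0), k0 = as.numeric(k0),
      cvObs = as.numeric(cvObs), densityHat = as.numeric(densityHat))
}

#' Required sample size for a target CV
#'
#' @slot cvTarget Target coefficient of variation.
#' @slot k Required number of points (real-valued).
#' @slot kInteger \code{k} rounded half-up to an integer.
#' @slot pilot The \linkS4class{PilotSummary} input.
#' @export
setClass("SampleSizeResult",
         representation(cvTarget = "numeric", k = "numeric",
                        kInteger = "integer", pilot = "PilotSummary"))
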