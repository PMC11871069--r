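# Accessors and show methods for the core classes.

#' @rdname distanceBinning
#' @param x A \linkS4class{DistanceBinning}.
#' @export
binEdges <- function(x) x@edges

#' @rdname distanceBinning
#' @export
nBins <- function(x) length(x@edges) - 1L

#' @rdname distanceBinning
#' @export
binMidpoints <- function(x) (x@edges[-1] + x@edges[-length(x@edges)]) / 2

#' @rdname distanceBinning
#' @export
binWidths <- function(x) diff(x@edges)

#' @rdname distanceBinning
#' @export
truncationRadius <- function(x) x@edges[length(x@edges)]

#' @rdname timeRemovalScheme
#' @param x A \linkS4class{TimeRemovalScheme}.
#' @export
nIntervals <- function(x) x@J

#' @rdname timeRemovalScheme
#' @export
intervalLabels <- function(x) x@labels

#' Detection records of a dataset
#' @param x A \linkS4class{PointCountDataset}.
#' @return data.frame of per-individual detection records.
#' @export
detections <- function(x) x@detections

#' Latent states of a simulated dataset
#' @param x A \linkS4class{SimulatedDataset}.
#' @return data.frame of latent N_super, N_pres, N_avail and counts y.
#' @export
latentStates <- function(x) x@latents

#' Per-survey observed counts
#'
#' Tabulates detections into the count matrix y indexed by
#' (point, year, visit), including zero-count surveys.
#'
#' @param x A \linkS4class{PointCountDataset}.
#' @return data.frame with columns point_id, refuge, year, visit, y.
#' @export
observedCounts <- function(x) {
  roster <- expand.grid(point_id = x@points$point_id, year = x@years,
                        visit = seq_len(x@nVisits),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  roster$refuge <- x@points$refuge[match(roster$point_id, x@points$point_id)]
  d <- x@detections
  key <- function(p, yr, v) paste(p, yr, v, sep = "\r")
  if (nrow(d)) {
    tab <- table(key(d$point_id, d$year, d$visit))
    roster$y <- as.integer(tab[key(roster$point_id, roster$year, roster$visit)])
    roster$y[is.na(roster$y)] <- 0L
  } else roster$y <- 0L
  roster[order(roster$point_id, roster$year, roster$visit),
         c("point_id", "refuge", "year", "visit", "y")]
}

#' Posterior summary table
#' @param x A \linkS4class{PosteriorSummary} or \linkS4class{TrendPosterior}.
#' @return data.frame of posterior moments, quantiles and diagnostics.
#' @export
posteriorSummary <- function(x) x@summary

#' Posterior draws
#' @param x A \linkS4class{PosteriorSummary} or \linkS4class{TrendPosterior}.
#' @return List of per-chain draw matrices.
#' @export
posteriorDraws <- function(x) x@draws

#' Fit flags
#' @param x A \linkS4class{PosteriorSummary} or \linkS4class{TrendPosterior}.
#' @return Character vector of warnings attached to the fit.
#' @export
fitFlags <- function(x) x@flags

#' Annual abundance summaries of a trend fit
#' @param x A \linkS4class{TrendPosterior}.
#' @return data.frame with one row per year.
#' @export
annualSummary <- function(x) x@annual

setMethod("show", "DistanceBinning", function(object) {
  cat("DistanceBinning:", nBins(object), "bins to",
      truncationRadius(object), "m\n")
  cat("  edges:", paste(binEdges(object), collapse = ", "), "\n")
})

setMethod("show", "TimeRemovalScheme", function(object) {
  cat("TimeRemovalScheme: J =", nIntervals(object), "\n")
  cat("  labels:", paste(intervalLabels(object), collapse = "; "), "\n")
})

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig\n")
  cat(sprintf("  lambda = %g, presence = %g, availability = %g (%s)\n",
              object@lambda, object@pPresence, object@availability,
              object@availabilityInterpretation))
  cat(sprintf("  K = %d points, T = %d visit(s), sigma = %g m\n",
              object@nPoints, object@nVisits, object@sigma))
})

setMethod("show", "PointCountDataset", function(object) {
  cat(class(object), "with", nrow(object@detections), "detections at",
      nrow(object@points), "points,",
      length(object@years), "year(s),", object@nVisits, "visit(s)\n")
})

setMethod("show", "PosteriorSummary", function(object) {
  cat("PosteriorSummary (", length(object@draws), "chains )\n")
  print(object@summary, digits = 3, row.names = FALSE)
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "TrendPosterior", function(object) {
  cat("TrendPosterior, AR order", object@spec@order, "\n")
  print(object@summary, digits = 3, row.names = FALSE)
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "SampleSizeResult", function(object) {
  cat(sprintf("Required points for CV %.2f: %.1f (rounded: %d)\n",
              object@cvTarget, object@k, object@kInteger))
})
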