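# Flat-file survey schema shared by simulated and field-style data, plus
# validation.  One CSV schema for detections; latent states and dataset
# metadata travel in sidecar files so a written dataset reads back whole.

.sidecarPaths <- function(path) {
  stem <- sub("\\.csv$", "", path)
  list(latents = paste0(stem, "_latents.csv"),
       meta = paste0(stem, "_meta.json"))
}

.configToList <- function(config) {
  list(lambda = config@lambda, pPresence = config@pPresence,
       availability = config@availability,
       availabilityInterpretation = config@availabilityInterpretation,
       nPoints = config@nPoints, nVisits = config@nVisits,
       sigma = config@sigma, edges = binEdges(config@binning),
       J = nIntervals(config@removal))
}

.configFromList <- function(x) {
  scenarioConfig(lambda = x$lambda, pPresence = x$pPresence,
                 availability = x$availability,
                 availabilityInterpretation = x$availabilityInterpretation,
                 nPoints = x$nPoints, nVisits = x$nVisits, sigma = x$sigma,
                 binning = distanceBinning(x$edges),
                 removal = timeRemovalScheme(x$J))
}

#' Write a point-count dataset to CSV
#'
#' Detections go to \code{path}; a \code{*_meta.json} sidecar records the
#' roster (points, years, visits), binning and removal scheme; for
#' simulated datasets a \code{*_latents.csv} sidecar carries the latent
#' states keyed by (point_id, year, visit).
#'
#' @param dataset A \linkS4class{PointCountDataset}.
#' @param path Output CSV path.
#' @return Invisibly, the paths written.
#' @export
writeDataset <- function(dataset, path) {
  stopifnot(is(dataset, "PointCountDataset"))
  sc <- .sidecarPaths(path)
  write.csv(dataset@detections[, .DET_COLS], path, row.names = FALSE,
            quote = FALSE)
  meta <- list(points = dataset@points, years = dataset@years,
               nVisits = dataset@nVisits, edges = binEdges(dataset@binning),
               J = nIntervals(dataset@removal))
  written <- c(detections = path, meta = sc$meta)
  if (is(dataset, "SimulatedDataset")) {
    write.csv(dataset@latents, sc$latents, row.names = FALSE, quote = FALSE)
    meta$config <- .configToList(dataset@config)
    meta$seed <- dataset@seed
    written <- c(written, latents = sc$latents)
  }
  jsonlite::write_json(meta, sc$meta, auto_unbox = TRUE, digits = NA)
  invisible(written)
}

.checkDetections <- function(det, nb, J, file = "input") {
  miss <- setdiff(.DET_COLS, names(det))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", file, paste(miss, collapse = ", ")))
  msgs <- character(0)
  # +1 for the header line when reporting file rows
  bad <- which(is.na(det$distance_class) | det$distance_class < 1 |
               det$distance_class > nb)
  if (length(bad))
    msgs <- c(msgs, sprintf("row %d: distance_class outside 1..%d",
                            bad + 1L, nb))
  bad <- which(is.na(det$time_interval) | det$time_interval < 1 |
               det$time_interval > J)
  if (length(bad))
    msgs <- c(msgs, sprintf("row %d: time_interval outside 1..%d", bad + 1L, J))
  msgs
}

#' Read a point-count dataset from CSV
#'
#' Reads detections written by \code{\link{writeDataset}}.  If the
#' metadata sidecar is present the full dataset (including the latent
#' sidecar for simulated data) is reconstructed; otherwise the roster is
#' inferred from the detections and the supplied schemes.
#'
#' @param path Detections CSV path.
#' @param binning,removal Schemes used when no metadata sidecar exists.
#' @return A \linkS4class{PointCountDataset}, or a
#'   \linkS4class{SimulatedDataset} when latents are available.
#' @export
readDataset <- function(path, binning = distanceBinning(),
                        removal = timeRemovalScheme()) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  sc <- .sidecarPaths(path)
  det <- read.csv(path, stringsAsFactors = FALSE)
  hasMeta <- file.exists(sc$meta)
  if (hasMeta) {
    meta <- jsonlite::read_json(sc$meta, simplifyVector = TRUE)
    binning <- distanceBinning(meta$edges)
    removal <- timeRemovalScheme(meta$J)
    pts <- as.data.frame(meta$points, stringsAsFactors = FALSE)
    years <- as.integer(meta$years)
    nVisits <- as.integer(meta$nVisits)
  }
  msgs <- .checkDetections(det, nBins(binning), nIntervals(removal),
                           file = basename(path))
  if (length(msgs)) stop(paste(msgs, collapse = "; "))
  if (nrow(det)) {
    det$point_id <- as.character(det$point_id)
    det$refuge <- as.character(det$refuge)
    det$species <- as.character(det$species)
    det$year <- as.integer(det$year)
    det$visit <- as.integer(det$visit)
    det$distance_class <- as.integer(det$distance_class)
    det$time_interval <- as.integer(det$time_interval)
  } else {
    det <- data.frame(refuge = character(), point_id = character(),
                      year = integer(), visit = integer(),
                      species = character(), distance_class = integer(),
                      time_interval = integer(), stringsAsFactors = FALSE)
  }
  if (!hasMeta) {
    pts <- unique(det[, c("point_id", "refuge")])
    if (nrow(pts) == 0L)
      pts <- data.frame(point_id = character(), refuge = character(),
                        stringsAsFactors = FALSE)
    years <- sort(unique(det$year))
    if (!length(years)) years <- 1L
    nVisits <- if (nrow(det)) max(det$visit) else 1L
  }
  base <- new("PointCountDataset", detections = det, points = pts,
              years = years, nVisits = as.integer(nVisits),
              binning = binning, removal = removal)
  if (hasMeta && !is.null(meta$config) && file.exists(sc$latents)) {
    lat <- read.csv(sc$latents, stringsAsFactors = FALSE)
    lat$point_id <- as.character(lat$point_id)
    return(new("SimulatedDataset", base, latents = lat,
               config = .configFromList(meta$config),
               seed = as.integer(meta$seed)))
  }
  base
}

#' Validate a survey CSV file
#'
#' Checks column presence, class ranges and count invariants without
#' constructing a dataset object.
#'
#' @param path Detections CSV path.
#' @param binning,removal Schemes defining valid class ranges (overridden
#'   by the metadata sidecar when present).
#' @return List with elements \code{ok} (logical), \code{messages}
#'   (row-level problems) and \code{nRecords}.
#' @export
validateDataset <- function(path, binning = distanceBinning(),
                            removal = timeRemovalScheme()) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  sc <- .sidecarPaths(path)
  if (file.exists(sc$meta)) {
    meta <- jsonlite::read_json(sc$meta, simplifyVector = TRUE)
    binning <- distanceBinning(meta$edges)
    removal <- timeRemovalScheme(meta$J)
  }
  det <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) e)
  if (inherits(det, "error"))
    return(list(ok = FALSE, messages = conditionMessage(det), nRecords = 0L))
  msgs <- tryCatch(.checkDetections(det, nBins(binning), nIntervals(removal),
                                    file = basename(path)),
                   error = function(e) conditionMessage(e))
  ok <- length(msgs) == 0L
  if (ok && nrow(det) == 0L)
    msgs <- "valid, but the file contains zero detection records"
  list(ok = ok, messages = msgs, nRecords = nrow(det))
}
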