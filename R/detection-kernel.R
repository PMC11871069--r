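# Closed-form detection and availability machinery shared by the simulator
# and both inference models.

#' Half-normal detection function
#'
#' Probability that an available individual at radial distance \code{r} is
#' detected: \code{g(r) = exp(-r^2 / (2 sigma^2))}.
#'
#' @param r Radial distance(s) in meters, >= 0.
#' @param sigma Half-normal scale in meters, > 0.
#' @return Detection probability in (0, 1]; \code{g(0) = 1}.
#' @examples
#' halfNormal(55, 55)   # exp(-1/2)
#' @export
halfNormal <- function(r, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(r < 0)) stop("r must be >= 0")
  exp(-r^2 / (2 * sigma^2))
}

#' Multinomial distance-cell probabilities under the rectangular rule
#'
#' Unconditional probability that an available individual is detected in
#' distance bin b: \code{pi_b = g(r_b) * 2 r_b delta_b / B^2}, with the
#' half-normal evaluated at the bin midpoint r_b (rectangular-rule
#' approximation to the integral of g(r) times the radial density
#' \code{f(r) = 2 r / B^2}).  Their sum is the overall perceptibility p_d.
#'
#' @param binning A \linkS4class{DistanceBinning}.
#' @param sigma Half-normal scale in meters.
#' @return Named list with \code{pi} (per-bin probabilities) and \code{p_d}
#'   (their sum).
#' @examples
#' distanceCellProbs(distanceBinning(), 55)$p_d   # ~0.267, prints as 0.27
#' @export
distanceCellProbs <- function(binning, sigma) {
  stopifnot(is(binning, "DistanceBinning"))
  if (sigma <= 0) stop("sigma must be > 0")
  r <- binMidpoints(binning)
  d <- binWidths(binning)
  B <- truncationRadius(binning)
  pi_d <- halfNormal(r, sigma) * 2 * r * d / B^2
  list(pi = pi_d, p_d = sum(pi_d))
}

#' Exact overall perceptibility for half-normal detection
#'
#' Analytic integral of \code{g(r) * 2 r / B^2} over \code{[0, B]}:
#' \code{(2 sigma^2 / B^2) * (1 - exp(-B^2 / (2 sigma^2)))}.  Serves as the
#' refinement oracle for the rectangular rule.
#'
#' @param sigma Half-normal scale in meters.
#' @param B Truncation radius in meters.
#' @return Exact detection probability within the truncation radius.
#' @export
closedFormPd <- function(sigma, B) {
  if (sigma <= 0 || B <= 0) stop("sigma and B must be > 0")
  s2 <- 2 * sigma^2
  (s2 / B^2) * (1 - exp(-B^2 / s2))
}

#' Conditional distance-cell probabilities
#'
#' Normalizes unconditional cells to the distribution of distance class
#' given detection: \code{pi_b / p_d}.
#'
#' @param pi Non-negative cell probabilities with positive sum.
#' @return Probabilities summing to 1.
#' @export
conditionalDistanceCells <- function(pi) {
  if (any(pi < 0)) stop("cell probabilities must be >= 0")
  s <- sum(pi)
  if (s <= 0) stop("degenerate input: all cells zero")
  pi / s
}

#' Geometric time-removal cells and overall availability
#'
#' Per-interval first-detection probabilities
#' \code{pi_j = p_a (1 - p_a)^(j-1)} for j = 1..J, whose sum is the overall
#' availability \code{phi = 1 - (1 - p_a)^J}.
#'
#' @param p_a Per-interval availability probability in (0, 1).
#' @param scheme A \linkS4class{TimeRemovalScheme}.
#' @return Named list with \code{pi} (removal cells), \code{phi}, and
#'   \code{conditional} (cells normalized by phi).
#' @examples
#' removalCellProbs(0.5)   # cells 0.5, 0.25, 0.125; phi = 0.875
#' @export
removalCellProbs <- function(p_a, scheme = timeRemovalScheme()) {
  if (p_a <= 0 || p_a >= 1) stop("p_a must be in (0,1)")
  J <- nIntervals(scheme)
  j <- seq_len(J)
  pi_a <- p_a * (1 - p_a)^(j - 1)
  phi <- 1 - (1 - p_a)^J
  list(pi = pi_a, phi = phi, conditional = pi_a / phi)
}

#' Per-interval availability from overall availability
#'
#' Inverse of \code{phi = 1 - (1 - p_a)^J}: returns
#' \code{p_a = 1 - (1 - phi)^(1/J)}.  Used when a scenario's availability
#' level is interpreted as overall availability.
#'
#' @param phi Overall availability in (0, 1).
#' @param J Number of removal intervals.
#' @return Per-interval availability p_a.
#' @export
perIntervalAvailability <- function(phi, J) {
  if (phi <= 0 || phi >= 1) stop("phi must be in (0,1)")
  if (J < 1) stop("J must be >= 1")
  1 - (1 - phi)^(1 / J)
}
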