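# Closed-form detection and availability machinery.

test_that("half-normal detection function matches its closed form", {
  expect_identical(halfNormal(0, 55), 1)
  expect_equal(halfNormal(55, 55), exp(-0.5))
  expect_equal(halfNormal(125, 55), exp(-125^2 / (2 * 55^2)))
  expect_equal(halfNormal(125, 55), 0.0756, tolerance = 1e-2)
  r <- seq(0, 150, by = 5)
  expect_true(all(diff(halfNormal(r, 55)) <= 0))
  expect_error(halfNormal(-1, 55), "r must be")
  expect_error(halfNormal(10, 0), "sigma")
})

test_that("rectangular-rule distance cells reproduce the survey detection probability", {
  dc <- distanceCellProbs(distanceBinning(), 55)
  # the four-bin 150 m scheme at sigma = 55 gives p_d ~ 0.267 (prints 0.27)
  expect_equal(round(dc$p_d, 2), 0.27)
  expect_equal(dc$p_d, 0.2667, tolerance = 1e-3)
  # hand-evaluated cell for the 50-100 m bin: g(75) * 2*75*50/150^2
  expect_equal(dc$pi[3], exp(-75^2 / (2 * 55^2)) * 2 * 75 * 50 / 150^2)
  expect_equal(dc$pi[3], 0.1315, tolerance = 1e-3)
  expect_true(all(dc$pi > 0 & dc$pi < 1))
  # sigma -> infinity: g -> 1 everywhere, p_d -> sum 2 r delta / B^2
  dcInf <- distanceCellProbs(distanceBinning(), 1e9)
  expect_equal(dcInf$p_d,
               sum(2 * binMidpoints(distanceBinning()) *
                     binWidths(distanceBinning()) / 150^2),
               tolerance = 1e-10)
})

test_that("closed-form p_d is the refinement limit of the rectangular rule", {
  expect_equal(closedFormPd(55, 150), 0.2624, tolerance = 1e-3)
  expect_equal(closedFormPd(1e8, 150), 1, tolerance = 1e-4)
  fine <- distanceBinning(seq(0, 150, by = 1))
  for (sig in c(30, 55, 90)) {
    expect_lt(abs(distanceCellProbs(fine, sig)$p_d - closedFormPd(sig, 150)),
              1e-4)
  }
})

test_that("p_d is increasing in sigma and within (0, 1]", {
  sigmas <- c(5, 15, 30, 55, 90, 200, 1e4)
  pds <- vapply(sigmas, function(s) distanceCellProbs(distanceBinning(), s)$p_d,
                numeric(1))
  expect_true(all(pds > 0 & pds <= 1))
  expect_true(all(diff(pds) > 0))
})

test_that("conditional distance cells normalize and preserve proportions", {
  expect_equal(conditionalDistanceCells(c(0.25, 0.25)), c(0.5, 0.5))
  dc <- distanceCellProbs(distanceBinning(), 55)
  cc <- conditionalDistanceCells(dc$pi)
  expect_equal(sum(cc), 1)
  expect_equal(cc, dc$pi / dc$p_d)
  expect_equal(conditionalDistanceCells(c(0.0267, 0.0661, 0.1315, 0.0420)),
               c(0.1001, 0.2478, 0.4931, 0.1575), tolerance = 2e-3)
  expect_error(conditionalDistanceCells(c(0, 0)), "degenerate")
  expect_error(conditionalDistanceCells(c(-0.1, 0.2)))
})

test_that("geometric removal cells conserve probability exactly", {
  rc <- removalCellProbs(0.5)
  expect_equal(rc$pi, c(0.5, 0.25, 0.125))
  expect_equal(rc$phi, 0.875)
  expect_equal(sum(rc$conditional), 1)
  expect_equal(removalCellProbs(0.8)$phi, 1 - 0.2^3)
  expect_equal(removalCellProbs(0.37, timeRemovalScheme(1))$phi, 0.37)
  # conservation: sum of cells + never-available mass = 1 exactly
  for (pa in c(0.05, 0.31, 0.5, 0.77, 0.99)) {
    rc <- removalCellProbs(pa)
    expect_equal(sum(rc$pi) + (1 - pa)^3, 1, tolerance = 1e-14)
  }
  expect_error(removalCellProbs(0), "p_a")
  expect_error(removalCellProbs(1), "p_a")
})

test_that("per-interval availability inverts overall availability", {
  expect_equal(perIntervalAvailability(0.875, 3), 0.5)
  expect_equal(perIntervalAvailability(0.42, 1), 0.42)
  expect_equal(perIntervalAvailability(0.992, 3), 0.8)
  # round trip to machine tolerance
  for (pa in seq(0.05, 0.95, by = 0.1)) {
    phi <- removalCellProbs(pa)$phi
    expect_equal(perIntervalAvailability(phi, 3), pa, tolerance = 1e-12)
  }
  expect_error(perIntervalAvailability(1.2, 3), "phi")
})

test_that("distance binning validates its geometry", {
  b <- distanceBinning()
  expect_equal(binMidpoints(b), c(12.5, 37.5, 75, 125))
  expect_equal(sum(binWidths(b)), truncationRadius(b))
  expect_error(distanceBinning(c(10, 25, 50)), "first edge")
  expect_error(distanceBinning(c(0, 50, 25)), "increasing")
  expect_error(timeRemovalScheme(0), "J")
})
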