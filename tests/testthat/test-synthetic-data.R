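# Synthetic-data generator: hierarchy invariants, determinism, calibration.

test_that("latent ordering holds for every record across scenarios", {
  for (cfg in list(scenarioConfig(nPoints = 60, nVisits = 3),
                   scenarioConfig(pPresence = 0.4, availability = 0.4,
                                  nPoints = 60),
                   scenarioConfig(availabilityInterpretation = "overall",
                                  nPoints = 40, nVisits = 2))) {
    d <- simulateDataset(cfg, seed = 11)
    l <- latentStates(d)
    expect_true(all(l$y <= l$N_avail))
    expect_true(all(l$N_avail <= l$N_pres))
    expect_true(all(l$N_pres <= l$N_super))
    expect_true(all(l$y >= 0))
    # detections table agrees with the latent y counts
    oc <- observedCounts(d)
    m <- merge(oc, l, by = c("point_id", "year", "visit"))
    expect_equal(m$y.x, m$y.y)
  }
})

test_that("same seed reproduces bit-identical data; seeds and K-growth behave", {
  cfg <- scenarioConfig(nPoints = 30, nVisits = 2)
  d1 <- simulateDataset(cfg, seed = 99)
  d2 <- simulateDataset(cfg, seed = 99)
  expect_identical(detections(d1), detections(d2))
  expect_identical(latentStates(d1), latentStates(d2))
  d3 <- simulateDataset(cfg, seed = 100)
  expect_false(identical(latentStates(d1), latentStates(d3)))
  # enlarging K leaves earlier points untouched (per-point streams)
  big <- simulateDataset(scenarioConfig(nPoints = 45, nVisits = 2), seed = 99)
  lb <- latentStates(big)
  expect_identical(lb[lb$point_id %in% latentStates(d1)$point_id, ],
                   latentStates(d1))
})

test_that("expected counts equal the analytic product of thinning factors", {
  expect_equal(expectedCounts(scenarioConfig(pPresence = 0.8,
                                             availability = 0.8)),
               5 * 0.8 * (1 - 0.2^3) * distanceCellProbs(distanceBinning(),
                                                         55)$p_d)
  expect_equal(expectedCounts(scenarioConfig(pPresence = 0.8,
                                             availability = 0.8)),
               1.058, tolerance = 1e-3)
  expect_equal(expectedCounts(scenarioConfig(pPresence = 0.4,
                                             availability = 0.4)),
               0.418, tolerance = 2e-3)
  # near-degenerate limits: no thinning
  cfg <- scenarioConfig(pPresence = 0.999999, availability = 0.999999,
                        sigma = 1e7)
  pdMax <- sum(2 * binMidpoints(distanceBinning()) *
                 binWidths(distanceBinning()) / 150^2)
  expect_equal(expectedCounts(cfg), 5 * pdMax, tolerance = 1e-4)
})

test_that("simulated means match analytic expectations within Monte-Carlo error", {
  # mean superpopulation at lambda = 5
  d <- simulateDataset(scenarioConfig(nPoints = 10000, nVisits = 1), seed = 3)
  l <- latentStates(d)
  se <- sqrt(5 / 10000)
  expect_lt(abs(mean(l$N_super) - 5), 3 * se)
  # detected counts per point-visit across the nine presence x availability
  # cells (moderate K per cell keeps this a seconds-scale check)
  for (pp in c(0.4, 0.6, 0.8)) for (av in c(0.4, 0.6, 0.8)) {
    cfg <- scenarioConfig(pPresence = pp, availability = av, nPoints = 2500)
    d <- simulateDataset(cfg, seed = 17)
    mu <- expectedCounts(cfg)
    obs <- mean(latentStates(d)$y)
    se <- sd(latentStates(d)$y) / sqrt(2500)
    expect_lt(abs(obs - mu), 3 * se)
  }
})

test_that("detection cell frequencies follow the product of conditional cells", {
  cfg <- scenarioConfig(pPresence = 0.8, availability = 0.8,
                        nPoints = 35000, nVisits = 3)
  d <- simulateDataset(cfg, seed = 5)
  det <- detections(d)
  expect_gt(nrow(det), 1e5)
  dc <- distanceCellProbs(distanceBinning(), 55)
  rc <- removalCellProbs(0.8)
  expected <- outer(dc$pi / dc$p_d, rc$pi / rc$phi)
  obs <- table(factor(det$distance_class, 1:4),
               factor(det$time_interval, 1:3))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = as.vector(expected)))
  expect_gt(gof$p.value, 0.01)
})

test_that("scenario grid is the full factorial cross with unique ids", {
  grid <- scenarioGrid(quiet = TRUE)
  expect_length(grid, 72)
  expect_false(anyDuplicated(names(grid)) > 0)
  expect_length(scenarioGrid(visits = 1L, quiet = TRUE), 36)
  expect_message(scenarioGrid(), "72 configurations")
  # every config distinct
  sigs <- vapply(grid, function(g)
    paste(g@pPresence, g@availability, g@nPoints, g@nVisits), character(1))
  expect_false(anyDuplicated(sigs) > 0)
})

test_that("trend simulator respects the AR mean and the latent ordering", {
  d <- simulateTrendDataset(nPoints = 40, nYears = 6, gamma = 0.6, seed = 2)
  l <- latentStates(d)
  expect_true(all(l$y <= l$N_avail & l$N_avail <= l$N_super))
  expect_setequal(unique(l$year), 1:6)
  # stationary mean: long trajectory averages near exp(beta0)
  d2 <- simulateTrendDataset(nPoints = 400, nYears = 30, gamma = 0.5,
                             beta0 = log(5), seed = 4)
  expect_equal(mean(latentStates(d2)$N_super), 5, tolerance = 0.05)
  expect_error(simulateTrendDataset(gamma = c(0.6, 0.5)), "sum")
})
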