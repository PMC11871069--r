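# Single-season fit: diagnostics, density conversion, posterior behaviour.

fastMcmc <- mcmcSettings(iterations = 2500, burnIn = 800, thin = 2)

test_that("gelmanRubin matches the between/within variance formula and coda", {
  set.seed(1)
  # identical chains: zero between-chain variance
  x <- rnorm(2000)
  expect_lte(gelmanRubin(list(x, x)), 1 + 1e-6)
  # same-distribution chains converge to 1
  chains <- replicate(3, rnorm(10000), simplify = FALSE)
  expect_lt(gelmanRubin(chains), 1.01)
  # disjoint chains blow up
  expect_gt(gelmanRubin(list(rnorm(500), rnorm(500) + 10)), 1.1)
  # cross-check against the independent coda implementation
  chains2 <- list(rnorm(5000), rnorm(5000, 0.05), rnorm(5000, -0.02, 1.1))
  ours <- gelmanRubin(chains2)
  codas <- coda::gelman.diag(coda::mcmc.list(lapply(chains2, coda::mcmc)),
                             autoburnin = FALSE)$psrf[1]
  expect_equal(ours, codas, tolerance = 0.005)
  expect_error(gelmanRubin(list(rnorm(100))), "2 chains")
  expect_error(gelmanRubin(list(rnorm(10), rnorm(20))), "equal length")
})

test_that("density conversion scales with the truncation area", {
  expect_equal(densityFromLambda(5, 150), 5 / (pi * 0.15^2))
  expect_equal(densityFromLambda(5, 150), 70.7, tolerance = 1e-3)
  expect_identical(densityFromLambda(0, 150), 0)
  expect_equal(densityFromLambda(5, 300), densityFromLambda(5, 150) / 4)
})

test_that("posterior respects parameter supports and recovers truth at the easy cell", {
  d <- simulateDataset(scenarioConfig(pPresence = 0.8, availability = 0.8,
                                      nPoints = 300, nVisits = 3), seed = 21)
  fit <- suppressWarnings(fitStatic(d, mcmc = fastMcmc, seed = 1))
  s <- posteriorSummary(fit)
  all <- do.call(rbind, posteriorDraws(fit))
  expect_true(all(all[, "p_a"] > 0 & all[, "p_a"] < 1))
  expect_true(all(all[, "p_p"] > 0 & all[, "p_p"] < 1))
  expect_true(all(all[, "sigma"] >= 1 & all[, "sigma"] <= exp(10)))
  expect_true(all(all[, "lambda"] > 0))
  expect_true(all(all[, "D"] >= 0))
  # quantiles ordered
  expect_true(all(s$q2.5 <= s$q50 & s$q50 <= s$q97.5))
  # the availability interval contains the generating value
  pa <- s[s$parameter == "p_a", ]
  expect_true(pa$q2.5 <= 0.8 && 0.8 <= pa$q97.5)
  sig <- s[s$parameter == "sigma", ]
  expect_true(sig$q2.5 <= 55 * 1.1 && 55 * 0.9 <= sig$q97.5)
  # density derived from the fit matches the exported converter
  dd <- deriveDensity(fit)
  expect_equal(dd$summary$mean, s$mean[s$parameter == "D"])
})

test_that("flat data reproduce the Beta(1,1) priors on p_a (prior recovery)", {
  d <- simulateDataset(scenarioConfig(lambda = 1e-4, nPoints = 15), seed = 2)
  expect_identical(nrow(detections(d)), 0L)
  fit <- suppressWarnings(fitStatic(d, mcmc = fastMcmc, seed = 3))
  expect_match(fitFlags(fit), "prior-dominated", all = FALSE)
  s <- posteriorSummary(fit)
  # Beta(1,1): mean 1/2, sd sqrt(1/12) ~ 0.289.  Zero counts still leak a
  # little information into p_a through the detection product, so the
  # posterior is only approximately the prior: absolute tolerances.
  pa <- s[s$parameter == "p_a", ]
  expect_lt(abs(pa$mean - 0.5), 0.06)
  expect_lt(abs(pa$sd - sqrt(1 / 12)), 0.03)
  pp <- s[s$parameter == "p_p", ]
  expect_lt(abs(pp$mean - 0.5), 0.08)
})

test_that("single-visit data flag weak identifiability of lambda and p_p", {
  d <- simulateDataset(scenarioConfig(nPoints = 80, nVisits = 1), seed = 5)
  fit <- suppressWarnings(fitStatic(d, mcmc = fastMcmc, seed = 1))
  expect_match(fitFlags(fit), "weakly-identified", all = FALSE)
  d3 <- simulateDataset(scenarioConfig(nPoints = 40, nVisits = 3), seed = 5)
  fit3 <- suppressWarnings(fitStatic(d3, mcmc = fastMcmc, seed = 1))
  expect_false(any(grepl("weakly-identified", fitFlags(fit3))))
})

test_that("with a single wide bin and interval, p_d concentrates at its ceiling", {
  # one bin to 150 m and one time interval carry no distance information;
  # with prior mass forced onto huge sigma, p_d -> 2*75*150/150^2 = 1
  cfg <- scenarioConfig(nPoints = 100, nVisits = 1,
                        binning = distanceBinning(c(0, 150)),
                        removal = timeRemovalScheme(1))
  d <- simulateDataset(cfg, seed = 9)
  fit <- suppressWarnings(fitStatic(
    d, priors = priorSpec(logSigmaRange = c(8, 10)),
    mcmc = fastMcmc, seed = 1))
  s <- posteriorSummary(fit)
  expect_equal(s$mean[s$parameter == "p_d"], 1, tolerance = 1e-3)
})

test_that("multi-year data are routed to the trend model", {
  d <- simulateTrendDataset(nPoints = 10, nYears = 3, seed = 1)
  expect_error(fitStatic(d), "fitTrend")
})
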