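# CV-based sample-size calculator and the packaged literature benchmark.

test_that("required points follow k = k0 (cv_obs / cv_target)^2", {
  expect_identical(requiredPoints(pilotSummary(50, 100, 0.30), 0.15)@kInteger,
                   400L)
  # fixed point: hitting the observed CV needs exactly the pilot size
  r <- requiredPoints(pilotSummary(200, 57, 0.2), 0.2)
  expect_equal(r@k, 57)
  expect_identical(r@kInteger, 57L)
  expect_error(requiredPoints(pilotSummary(0, 10, 0.3), 0.15),
               "encounter rate")
  expect_error(requiredPoints(pilotSummary(10, 10, 0.3), -1), "cvTarget")
})

test_that("the requirement depends on the pilot only through k0 and cv_obs", {
  set.seed(4)
  for (i in 1:25) {
    k0 <- sample(20:2000, 1)
    cv <- runif(1, 0.05, 1.5)
    ct <- runif(1, 0.05, 0.5)
    k1 <- requiredPoints(pilotSummary(sample(1:5000, 1), k0, cv), ct)@k
    k2 <- requiredPoints(pilotSummary(sample(1:5000, 1), k0, cv), ct)@k
    expect_equal(k1, k2)
    expect_equal(k1, k0 * (cv / ct)^2)
  }
})

test_that("requirements are monotone in target and observed CV", {
  p <- pilotSummary(120, 90, 0.4)
  k <- vapply(c(0.1, 0.15, 0.2, 0.25, 0.4),
              function(ct) requiredPoints(p, ct)@k, numeric(1))
  expect_true(all(diff(k) < 0))
  k2 <- vapply(c(0.1, 0.3, 0.5, 0.9),
               function(cv) requiredPoints(pilotSummary(120, 90, cv), 0.15)@k,
               numeric(1))
  expect_true(all(diff(k2) > 0))
})

test_that("CV rescaling reproduces the published paired requirement columns", {
  # research-grade (0.15) means rescaled to monitoring-grade (0.25)
  expect_identical(cvScaling(1257, 0.15, 0.25), 453)
  expect_identical(cvScaling(386, 0.15, 0.25), 139)
  expect_identical(cvScaling(133, 0.15, 0.25), 48)
  expect_identical(cvScaling(670, 0.15, 0.25), 241)
  expect_identical(cvScaling(77, 0.3, 0.3), 77)
  # exact 25/9 ratio identity before rounding
  for (k in c(13, 240, 1111)) {
    expect_equal(cvScaling(k, 0.25, 0.15, round = FALSE),
                 k * 25 / 9)
    expect_equal(cvScaling(k, 0.15, 0.25, round = FALSE) * (25 / 9), k,
                 tolerance = 1e-12)
  }
})

test_that("encounter rate is detections per point", {
  expect_equal(encounterRate(pilotSummary(50, 100, 0.3)), 0.5)
  expect_equal(encounterRate(pilotSummary(0, 10, 0.3)), 0)
  expect_equal(encounterRate(pilotSummary(668, 91, 0.3)), 7.34, tolerance = 1e-3)
})

test_that("the requirement surface bins pilots into the figure classes", {
  single <- xyzTable(list(pilotSummary(60, 80, 0.35)))
  expect_identical(nrow(single), 2L)  # one cell per target CV
  expect_equal(single$median_k[single$cv_target == 0.15],
               80 * (0.35 / 0.15)^2)
  # cell-wise ratio between the two targets
  pilots <- list(pilotSummary(30, 50, 0.2), pilotSummary(400, 120, 0.5),
                 pilotSummary(1500, 260, 0.12))
  tab <- xyzTable(pilots)
  t15 <- tab[tab$cv_target == 0.15, ]
  t25 <- tab[tab$cv_target == 0.25, ]
  expect_equal(t15$median_k, t25$median_k * (0.25 / 0.15)^2)
  # sparse pilot with high CV lands beyond 2000 required points
  hi <- xyzTable(list(pilotSummary(50, 500, 0.65)))
  k15 <- hi$median_k[hi$cv_target == 0.15]
  expect_equal(k15, 500 * (0.65 / 0.15)^2)
  expect_gt(k15, 2000)
  expect_match(as.character(hi$k_class[hi$cv_target == 0.15]), "2e\\+03|2000")
})

test_that("literature benchmark lookups return the packaged rows", {
  tab <- literatureTable()
  expect_true(all(c("species", "avg_min_n", "range_lo", "range_hi",
                    "references") %in% names(tab)))
  acfl <- literatureLookup("Acadian Flycatcher")
  expect_identical(acfl$avg_min_n, 94L)
  expect_identical(acfl$range_lo, 23L)
  expect_identical(acfl$range_hi, 287L)
  expect_identical(literatureLookup("Swainson's Warbler")$avg_min_n, 61L)
  multi <- literatureLookup("multispecies")
  expect_identical(multi$avg_min_n, 241L)
  expect_identical(multi$range_lo, 20L)
  expect_identical(multi$range_hi, 828L)
  # case-insensitive
  expect_identical(literatureLookup("wood thrush")$avg_min_n, 135L)
  expect_error(literatureLookup("Dodo"), "Nearest matches")
})
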