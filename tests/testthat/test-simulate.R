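test_that("simulated covariates respect the design envelopes and reproduce under a seed", {
  scn <- simulationScenario(seed = 17)
  c1 <- simulateCovariates(scn)
  c2 <- simulateCovariates(scn)
  expect_identical(c1, c2)
  expect_true(all(c1$wetlands$size >= 0.28 & c1$wetlands$size <= 32.4))
  expect_equal(sum(c1$wetlands$type == "ACEP"), 20L)
  expect_equal(nrow(c1$wetlands), 33L)
  pts <- table(c1$siteCovs$wetland[c1$siteCovs$year == "1"])
  expect_true(all(pts >= 1 & pts <= 9))
  expect_silent(validateSiteCovariates(c1$siteCovs))
  expect_silent(validateSurveyCovariates(c1$surveyCovs))
  expect_true(all(c1$surveyCovs$time >= 6.85 & c1$surveyCovs$time <= 15.22))
  expect_true(all(c1$surveyCovs$day >= 1 & c1$surveyCovs$day <= 102))
})

test_that("categorical proportions approach their targets at large n", {
  scn <- simulationScenario(nWetlands = 700, nACEP = 420,
                            meanPointsPerWetland = 8, seed = 18)
  cc <- simulateCovariates(scn)
  n <- nrow(cc$siteCovs)
  expect_gt(n, 8000)
  p1 <- mean(cc$siteCovs$shrub1 == "0-50")
  expect_equal(p1, 0.77, tolerance = 0.02)
  expect_equal(mean(cc$surveyCovs$sky == "0-1"), 0.56, tolerance = 0.02)
  expect_equal(mean(cc$siteCovs$herb == "76-100"), 0.52, tolerance = 0.02)
})

test_that("detection histories obey the latent-state generative model", {
  covs <- simulateCovariates(simulationScenario(nWetlands = 10, seed = 19))
  sat <- simulateDetections(covs, c("(Intercept)" = 50),
                            c("(Intercept)" = 50), seed = 19)
  expect_true(all(sat$det@y == 1L))
  none <- simulateDetections(covs, c("(Intercept)" = -50),
                             c("(Intercept)" = 50), seed = 19)
  expect_true(all(none$det@y == 0L))
  expect_true(all(none$z == 0L))

  # unoccupied site-units never produce detections
  mid <- simulateDetections(covs, c("(Intercept)" = 0.2, size = 1),
                            c("(Intercept)" = 0.5), seed = 20)
  detected <- rowSums(mid$det@y, na.rm = TRUE) > 0
  expect_true(all(mid$z[detected] == 1L))

  expect_error(simulateDetections(covs, c(elevation = 1),
                                  c("(Intercept)" = 0), seed = 1),
               "alpha truth names")
})

test_that("naive occupancy matches its detection-adjusted closed form", {
  scn <- simulationScenario(nWetlands = 1250, nACEP = 750,
                            meanPointsPerWetland = 4, seed = 23)
  covs <- simulateCovariates(scn)
  psi <- 0.6; p <- 0.7
  sim <- simulateDetections(covs,
                            c("(Intercept)" = stats::qlogis(psi)),
                            c("(Intercept)" = stats::qlogis(p)), seed = 23)
  n <- nSiteUnits(sim$det)
  expect_gt(n, 5000)
  expected <- psi * (1 - (1 - p)^2)       # 0.546
  se <- sqrt(expected * (1 - expected) / n)
  expect_equal(naiveOccupancy(sim$det), expected, tolerance = 3 * se / expected)
})

test_that("simulated richness is Poisson with the requested mean", {
  wet <- data.frame(wetland = sprintf("W%04d", 1:500),
                    type = rep(c("ACEP", "reference"), 250),
                    size = exp(stats::runif(500, log(0.28), log(32.4))))
  r1 <- simulateRichness(wet, c(intercept = log(10), type = 0, size = 0,
                                year = 0), nYears = 2, seed = 29)
  expect_identical(r1, simulateRichness(wet, c(intercept = log(10), type = 0,
                                               size = 0, year = 0),
                                        nYears = 2, seed = 29))
  expect_equal(mean(r1$richness), 10, tolerance = 0.03)

  wetBig <- data.frame(wetland = sprintf("W%05d", 1:5000),
                       type = "ACEP", size = exp(stats::rnorm(5000)))
  r2 <- simulateRichness(wetBig, c(intercept = log(10), type = 0, size = 0,
                                   year = 0), nYears = 2, seed = 31)
  dispersion <- stats::var(r2$richness) / mean(r2$richness)
  expect_gt(dispersion, 0.9)
  expect_lt(dispersion, 1.1)
})

test_that("a full study is reproducible and internally consistent", {
  s1 <- simulateStudy(simulationScenario(nWetlands = 6, nACEP = 4, seed = 37))
  s2 <- simulateStudy(simulationScenario(nWetlands = 6, nACEP = 4, seed = 37))
  expect_identical(s1$detections$sosp@y, s2$detections$sosp@y)
  expect_identical(s1$richness, s2$richness)
  expect_setequal(names(s1$detections), c("sosp", "swsp", "deju", "wtsp"))
  expect_equal(nrow(s1$richness), 12L)
  for (sp in names(s1$detections))
    expect_true(validObject(s1$detections[[sp]]))
})
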