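test_that("categorical covariates are dummy-coded against the first level", {
  det <- makeDet(matrix(c(1, 0, 0, 0, 1, 0), nrow = 3),
                 point = c("P1", "P2", "P3"))
  sc <- makeSiteCovs(c("P1", "P2", "P3"), type = c("ACEP", "ACEP", "reference"))
  vc <- makeSurveyCovs(c("P1", "P2", "P3"))
  des <- buildDesign(det, sc, vc, modelSpec("sosp", occupancy = "type"))
  expect_identical(unname(des@X),
                   matrix(c(1, 1, 1, 0, 0, 1), nrow = 3))
  expect_identical(colnames(des@X), c("(Intercept)", "typereference"))
  expect_identical(des@encoding$occupancy$type$reference, "ACEP")
})

test_that("continuous covariates are z-standardized and the record inverts", {
  det <- makeDet(matrix(c(1, 0, 0, 0, 1, 0), nrow = 3),
                 point = c("P1", "P2", "P3"))
  sc <- makeSiteCovs(c("P1", "P2", "P3"), size = c(1, 2, 3))
  vc <- makeSurveyCovs(c("P1", "P2", "P3"))
  des <- buildDesign(det, sc, vc, modelSpec("sosp", occupancy = "size",
                                            detection = "wind"))
  expect_equal(unname(des@X[, "size"]), c(-1, 0, 1))
  expect_equal(mean(des@X[, "size"]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(des@X[, "size"]), 1, tolerance = 1e-12)
  e <- des@encoding$occupancy$size
  expect_equal(des@X[, "size"] * e$sd + e$mean, sc$size,
               tolerance = 1e-12, ignore_attr = TRUE)
  ew <- des@encoding$detection$wind
  expect_equal(des@W[, "wind"] * ew$sd + ew$mean,
               makeSurveyCovs(c("P1", "P2", "P3"))$wind,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("re-applying a stored encoding reproduces the matrices exactly", {
  st <- simulateStudy(simulationScenario(nWetlands = 6, nACEP = 4, seed = 8))
  spec <- globalModelSpec("sosp")
  d1 <- buildDesign(st$detections$sosp, st$siteCovs, st$surveyCovs, spec)
  d2 <- buildDesign(st$detections$sosp, st$siteCovs, st$surveyCovs, spec,
                    encoding = d1@encoding)
  expect_identical(d2@X, d1@X)
  expect_identical(d2@W, d1@W)
})

test_that("degenerate or unknown covariate inputs are rejected", {
  det <- makeDet(matrix(c(1, 0, 0, 0, 1, 0), nrow = 3),
                 point = c("P1", "P2", "P3"))
  vc <- makeSurveyCovs(c("P1", "P2", "P3"))
  scConst <- makeSiteCovs(c("P1", "P2", "P3"), size = c(2, 2, 2))
  expect_error(buildDesign(det, scConst, vc, modelSpec("sosp", "size")),
               "zero variance")
  scBad <- makeSiteCovs(c("P1", "P2", "P3"))
  scBad$herb[2] <- "plenty"
  expect_error(buildDesign(det, scBad, vc, modelSpec("sosp", "herb")),
               "unknown level 'plenty'")
  expect_error(buildDesign(det, makeSiteCovs(c("P1", "P2")), vc,
                           modelSpec("sosp", "size")),
               "site covariates missing")
})

test_that("design row counts follow site-units and realized visits", {
  y <- matrix(c(1L, NA, 0L, 0L, 1L, NA), nrow = 3)
  det <- makeDet(y, point = c("P1", "P2", "P3"))
  sc <- makeSiteCovs(c("P1", "P2", "P3"))
  vc <- makeSurveyCovs(c("P1", "P2", "P3"))
  des <- buildDesign(det, sc, vc, modelSpec("sosp", "size", "wind"))
  expect_equal(nrow(des@X), 3L)
  expect_equal(nrow(des@W), sum(!is.na(y)))
  expect_equal(des@visitIndex$y, c(1L, 0L, 1L, 0L))
  # W means/SDs are computed over realized visits only
  expect_equal(mean(des@W[, "wind"]), 0, tolerance = 1e-12)
})

test_that("collinearity screen flags perfect correlation and tolerates constants", {
  sc <- makeSiteCovs(sprintf("P%d", 1:6), size = c(1, 2, 3, 4, 5, 6))
  sc$herb <- c("0-25", "26-75", "76-100", "0-25", "26-75", "76-100")
  rep1 <- checkCollinearity(sc, covariates = c("size", "herb"))
  expect_false(any(rep1$flagged))

  # identical and negated copies via the level codes
  sc$shrub1 <- ifelse(sc$herb == "0-25", "0-50", "51-100")
  sc$water <- ifelse(sc$size > 3, "present", "absent")
  sc$size2 <- -sc$size   # not a registry covariate: numeric passthrough
  rep2 <- checkCollinearity(sc, covariates = c("size", "size2"))
  expect_equal(rep2$r, 1.0, tolerance = 1e-12)
  expect_true(all(rep2$flagged))

  scc <- sc; scc$woody <- "absent"
  rep3 <- checkCollinearity(scc, covariates = c("size", "woody"))
  expect_true(is.na(rep3$r))
  expect_false(any(rep3$flagged))

  expect_error(checkCollinearity(sc[1:2, ], covariates = c("size", "herb")),
               "three rows")
})

test_that("independent simulated covariates stay under the 0.5 screen", {
  set.seed(41)
  n <- 1000
  a <- stats::rnorm(n); b <- stats::rnorm(n)
  df <- makeSiteCovs(sprintf("P%04d", 1:n), size = exp(a))
  df$other <- b
  rep <- checkCollinearity(df, covariates = c("size", "other"))
  # textbook sum-formula correlation, computed independently
  x <- as.numeric(df$size); yv <- b
  rHand <- abs((sum(x * yv) - n * mean(x) * mean(yv)) /
               ((n - 1) * stats::sd(x) * stats::sd(yv)))
  expect_equal(rep$r, rHand, tolerance = 1e-12)
  expect_lt(rep$r, 0.5)
  expect_false(rep$flagged)
})
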