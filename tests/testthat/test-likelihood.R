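test_that("invLogit is a stable, symmetric link", {
  expect_identical(invLogit(0), 0.5)
  x <- c(-7.3, -1, 0.2, 4, 12)
  expect_equal(invLogit(x) + invLogit(-x), rep(1, length(x)), tolerance = 1e-12)
  expect_equal(invLogit(40), 1, tolerance = 1e-12)
  expect_equal(invLogit(-40), 0, tolerance = 1e-12)
  expect_true(all(diff(invLogit(seq(-30, 30, by = 0.5))) >= 0))
})

test_that("the site marginal likelihood matches hand values and the enumeration oracle", {
  expect_equal(siteMarginalLikelihood(0.5, c(0.5, 0.5), c(0, 0)), 0.625,
               tolerance = 1e-12)
  expect_equal(siteMarginalLikelihood(0.5, c(0.5, 0.5), c(1, 0)), 0.125,
               tolerance = 1e-12)
  expect_error(siteMarginalLikelihood(0.5, c(0.5, 0.5), c(2, 0)),
               "only 0 and 1")

  set.seed(101)
  for (i in 1:200) {
    J <- sample(1:4, 1)
    psi <- stats::runif(1, 0.01, 0.99)
    p <- stats::runif(J, 0.01, 0.99)
    y <- stats::rbinom(J, 1, 0.5)
    expect_equal(siteMarginalLikelihood(psi, p, y), enumMarginal(psi, p, y),
                 tolerance = 1e-12)
  }
})

test_that("the marginal likelihood is invariant to visit order", {
  set.seed(7)
  psi <- 0.37; p <- c(0.2, 0.6, 0.9); y <- c(1, 0, 0)
  for (i in 1:5) {
    o <- sample(3)
    expect_equal(siteMarginalLikelihood(psi, p[o], y[o]),
                 siteMarginalLikelihood(psi, p, y), tolerance = 1e-14)
  }
})

test_that("the latent-state conditional matches its closed form and limits", {
  expect_equal(conditionalZProbability(0.5, c(0.5, 0.5), c(0, 0)), 0.2,
               tolerance = 1e-12)
  expect_equal(conditionalZProbability(0.5, c(0.5, 0.5), c(1, 0)), 1)
  # monotone decrease to 0 as psi -> 0 with an all-zero history
  psis <- c(0.5, 0.1, 0.01, 0.001, 1e-6)
  pz <- sapply(psis, conditionalZProbability, p = c(0.5, 0.5), y = c(0, 0))
  expect_true(all(diff(pz) < 0))
  expect_lt(pz[length(pz)], 1e-5)
})

test_that("the joint log-likelihood equals an explicit per-site loop", {
  st <- simulateStudy(simulationScenario(nWetlands = 7, nACEP = 4, seed = 21))
  des <- buildDesign(st$detections$swsp, st$siteCovs, st$surveyCovs,
                     modelSpec("swsp", c("type", "size"), c("wind", "sky")))
  set.seed(22)
  params <- list(alpha = stats::rnorm(ncol(des@X)),
                 beta = stats::rnorm(ncol(des@W)))
  psi <- invLogit(drop(des@X %*% params$alpha))
  p <- invLogit(drop(des@W %*% params$beta))
  vi <- des@visitIndex
  loop <- sum(sapply(seq_len(nrow(des@X)), function(i) {
    rows <- which(vi$site == i)
    log(siteMarginalLikelihood(psi[i], p[rows], vi$y[rows]))
  }))
  expect_equal(logLikelihood(params, des), loop, tolerance = 1e-10)

  # one site, all coefficients zero: psi = p = 0.5, y = (0, 0)
  det1 <- makeDet(matrix(c(0L, 0L), nrow = 1), point = "P1")
  des1 <- buildDesign(det1, makeSiteCovs("P1"), makeSurveyCovs("P1"),
                      modelSpec("sosp"))
  expect_equal(logLikelihood(list(alpha = 0, beta = 0), des1), log(0.625),
               tolerance = 1e-12)

  expect_error(logLikelihood(list(alpha = c(0, 0), beta = 0), des1),
               "alpha length")
})

test_that("with perfect detection the intercept-only MLE is naive occupancy", {
  st <- simulateStudy(simulationScenario(nWetlands = 10, seed = 31))
  det <- st$detections$sosp
  nv <- naiveOccupancy(det)
  anyDet <- rowSums(det@y == 1, na.rm = TRUE) > 0
  f <- function(psi) sum(ifelse(anyDet, log(psi), log(1 - psi)))
  opt <- stats::optimize(f, c(1e-4, 1 - 1e-4), maximum = TRUE)
  expect_equal(opt$maximum, nv, tolerance = 1e-4)
})

test_that("pointwise log-likelihood rows agree with the joint likelihood", {
  st <- simulateStudy(simulationScenario(nWetlands = 6, nACEP = 4, seed = 41))
  des <- buildDesign(st$detections$deju, st$siteCovs, st$surveyCovs,
                     modelSpec("deju", "size", "time"))
  set.seed(42)
  K <- ncol(des@X) + ncol(des@W)
  dr <- matrix(stats::rnorm(6 * K, sd = 0.5), nrow = 6)
  dr[2, ] <- dr[1, ]   # identical draws give identical rows
  post <- new("OccuPosterior", draws = dr, chain = rep(1:2, each = 3),
              config = list(), acceptance = 0.3, scales = 0.5)
  pw <- pointwiseLogLik(post, des)
  expect_equal(dim(pw), c(6L, nrow(des@X)))
  expect_identical(pw[1, ], pw[2, ])
  jl <- sapply(seq_len(nrow(dr)), function(s)
    logLikelihood(list(alpha = dr[s, seq_len(ncol(des@X))],
                       beta = dr[s, -seq_len(ncol(des@X))]), des))
  expect_equal(rowSums(pw), jl, tolerance = 1e-10)
  expect_equal(mean(rowSums(pw)), mean(jl), tolerance = 1e-12)
})
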