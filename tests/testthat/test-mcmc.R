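test_that("the logistic prior density and its symmetry hold", {
  expect_equal(logPrior(0), log(0.25), tolerance = 1e-12)
  x <- c(-3.2, -0.7, 0.1, 1.4, 6)
  expect_equal(logPrior(x), logPrior(-x), tolerance = 1e-12)
  expect_equal(logPrior(list(alpha = c(0, 1), beta = -1)),
               logPrior(c(0, 1, -1)), tolerance = 1e-12)
})

test_that("retained-sample bookkeeping matches the closed-form count", {
  for (cs in list(c(100, 20, 1), c(101, 20, 3), c(1000, 250, 5),
                  c(37, 5, 7), c(60, 0, 9))) {
    cfg <- mcmcConfig(nChains = 2, nIterations = cs[1], nBurnin = cs[2],
                      thin = cs[3], seed = 4)
    expect_equal(cfg$retainedPerChain, (cs[1] - cs[2]) %/% cs[3])
    post <- samplePrior(cfg, nCoef = 1)
    expect_equal(nrow(draws(post)), 2L * ((cs[1] - cs[2]) %/% cs[3]))
    expect_equal(as.integer(table(chainIds(post))),
                 rep((cs[1] - cs[2]) %/% cs[3], 2L))
  }
  expect_error(mcmcConfig(nIterations = 100, nBurnin = 100), "nBurnin")
  expect_error(mcmcConfig(nIterations = 100, nBurnin = 99, thin = 5),
               "no retained samples")
  expect_error(mcmcConfig(thin = 0), "thin")
})

test_that("runs are bit-identical under the same seed", {
  st <- simulateStudy(simulationScenario(nWetlands = 6, nACEP = 4, seed = 13))
  des <- buildDesign(st$detections$sosp, st$siteCovs, st$surveyCovs,
                     modelSpec("sosp", "size", "day"))
  cfg <- mcmcConfig(nChains = 2, nIterations = 300, nBurnin = 100, thin = 2,
                    seed = 77)
  p1 <- runChains(des, cfg)
  p2 <- runChains(des, cfg)
  expect_identical(draws(p1), draws(p2))
  expect_identical(p1@acceptance, p2@acceptance)
  p3 <- runChains(des, mcmcConfig(nChains = 2, nIterations = 300,
                                  nBurnin = 100, thin = 2, seed = 78))
  expect_false(identical(draws(p1), draws(p3)))
  expect_true(all(p1@acceptance >= 0 & p1@acceptance <= 1))
})

test_that("split R-hat is near 1 for well-mixed chains and large for disjoint ones", {
  set.seed(55)
  n <- 5000
  good <- new("OccuPosterior",
              draws = matrix(stats::rnorm(4 * n), ncol = 1,
                             dimnames = list(NULL, "a")),
              chain = rep(1:4, each = n), config = list(),
              acceptance = 0.3, scales = 0.5)
  expect_lt(gelmanRhat(good)[["a"]], 1.01)
  # the classic estimator can dip below 1 by O(1/n) sampling noise
  expect_gte(gelmanRhat(good)[["a"]], 0.99)

  apart <- new("OccuPosterior",
               draws = matrix(c(stats::rnorm(n, -5), stats::rnorm(n, 5)),
                              ncol = 1, dimnames = list(NULL, "a")),
               chain = rep(1:2, each = n), config = list(),
               acceptance = 0.3, scales = 0.5)
  expect_gt(gelmanRhat(apart)[["a"]], 1.1)

  single <- new("OccuPosterior",
                draws = matrix(stats::rnorm(n), ncol = 1,
                               dimnames = list(NULL, "a")),
                chain = rep(1L, n), config = list(),
                acceptance = 0.3, scales = 0.5)
  expect_error(gelmanRhat(single), "two chains")

  flat <- new("OccuPosterior",
              draws = matrix(1, 40, 1, dimnames = list(NULL, "a")),
              chain = rep(1:2, each = 20), config = list(),
              acceptance = 0.3, scales = 0.5)
  expect_true(is.na(gelmanRhat(flat)[["a"]]))
})

test_that("posterior summaries use type-7 equal-tailed quantiles", {
  x <- c(1, 2, 3, 4, 5)
  post <- new("OccuPosterior",
              draws = matrix(x, ncol = 1, dimnames = list(NULL, "a")),
              chain = rep(1L, 5), config = list(),
              acceptance = 0.3, scales = 0.5)
  sm <- summarizePosterior(post)
  expect_equal(sm$lower95, stats::quantile(x, 0.025, names = FALSE, type = 7))
  expect_equal(sm$upper95, stats::quantile(x, 0.975, names = FALSE, type = 7))
  expect_equal(sm$lower50, stats::quantile(x, 0.25, names = FALSE, type = 7))
  expect_equal(sm$mean, 3)
  expect_equal(sm$median, 3)
  expect_true(sm$lower95 <= sm$lower50 && sm$upper50 <= sm$upper95)

  const <- new("OccuPosterior",
               draws = matrix(2.5, 20, 1, dimnames = list(NULL, "a")),
               chain = rep(1L, 20), config = list(),
               acceptance = 0.3, scales = 0.5)
  smc <- summarizePosterior(const)
  expect_equal(c(smc$lower50, smc$upper50, smc$lower95, smc$upper95),
               rep(2.5, 4))

  set.seed(9)
  sym <- stats::rnorm(20000)
  sym <- c(sym, -sym)  # exactly symmetric about 0
  postS <- new("OccuPosterior",
               draws = matrix(sym, ncol = 1, dimnames = list(NULL, "a")),
               chain = rep(1:2, each = 20000), config = list(),
               acceptance = 0.3, scales = 0.5)
  smS <- summarizePosterior(postS)
  expect_equal(smS$lower95, -smS$upper95, tolerance = 1e-8)
  expect_equal(smS$mean, 0, tolerance = 1e-12)
})

test_that("the sampler agrees distributionally with an independent Gibbs engine", {
  scn <- simulationScenario(nWetlands = 40, meanPointsPerWetland = 4, seed = 11)
  covs <- simulateCovariates(scn)
  sim <- simulateDetections(covs, c("(Intercept)" = 0.405),
                            c("(Intercept)" = 0.847), seed = 11)
  des <- buildDesign(sim$det, covs$siteCovs, covs$surveyCovs, modelSpec("sosp"))
  post <- runChains(des, mcmcConfig(nChains = 4, nIterations = 6000,
                                    nBurnin = 1000, thin = 5, seed = 2))
  mine <- colMeans(draws(post))
  mineSD <- apply(draws(post), 2, stats::sd)

  suppressMessages(requireNamespace("rjags"))
  y <- sim$det@y
  model <- "model{
    a ~ dlogis(0, 1); b ~ dlogis(0, 1)
    for (i in 1:n) {
      z[i] ~ dbern(ilogit(a))
      for (j in 1:2) { y[i, j] ~ dbern(z[i] * ilogit(b)) }
    }}"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = y, n = nrow(y)),
                          inits = list(z = apply(y, 1, max),
                                       .RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 5),
                          n.chains = 2, quiet = TRUE)
  stats::update(jm, 2000)
  s <- rjags::coda.samples(jm, c("a", "b"), 10000, thin = 5)
  ref <- summary(s)$statistics
  expect_equal(unname(mine[1]), ref["a", "Mean"], tolerance = 0.08)
  expect_equal(unname(mine[2]), ref["b", "Mean"], tolerance = 0.08)
  expect_equal(unname(mineSD[1]), ref["a", "SD"], tolerance = 0.25)
  expect_equal(unname(mineSD[2]), ref["b", "SD"], tolerance = 0.25)
})
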