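# Small in-code fixtures shared across test files.

makeDet <- function(y, point = sprintf("P%d", seq_len(nrow(y))),
                    year = rep("1", nrow(y)),
                    wetland = rep("W1", nrow(y)), species = "sosp") {
  y <- matrix(as.integer(y), nrow = nrow(y))
  new("DetectionTable", species = species,
      siteId = paste(point, year, sep = "_"), pointId = point,
      wetlandId = wetland, year = factor(year, levels = c("1", "2")), y = y)
}

makeSiteCovs <- function(point, year = rep("1", length(point)),
                         type = "ACEP", size = seq_along(point) + 0.5,
                         herb = "0-25", shrub1 = "0-50", bareground = "0-50",
                         woody = "absent", water = "absent", shrub5 = "0-25") {
  data.frame(point = point, year = year, type = type, size = size,
             herb = herb, shrub1 = shrub1, bareground = bareground,
             woody = woody, water = water, shrub5 = shrub5,
             stringsAsFactors = FALSE)
}

makeSurveyCovs <- function(point, year = "1", visits = 1:2) {
  g <- expand.grid(point = point, year = year, visit = visits,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[order(g$point, g$year, g$visit), , drop = FALSE]
  n <- nrow(g)
  g$time <- seq(7, 15, length.out = n)
  g$sky <- rep(c("0-1", "2-3"), length.out = n)
  g$wind <- seq(0, 3, length.out = n)
  g$temp <- seq(-5, 10, length.out = n)
  g$dist <- seq(10, 50, length.out = n)
  g$day <- seq(1, 100, length.out = n)
  rownames(g) <- NULL
  g
}

# a fit whose posterior draws are constructed, for deterministic checks of
# the reduction rule and derived quantities
constructedFit <- function(drawsOverride = list(),
                           specOcc = c("type", "size"),
                           specDet = c("day"), seed = 99, nDraws = 400) {
  scn <- simulationScenario(nWetlands = 8, nACEP = 5, seed = seed)
  covs <- simulateCovariates(scn, seed = seed)
  sim <- simulateDetections(covs, c("(Intercept)" = 0.3),
                            c("(Intercept)" = 0.4), seed = seed)
  spec <- modelSpec("sosp", occupancy = specOcc, detection = specDet)
  des <- buildDesign(sim$det, covs$siteCovs, covs$surveyCovs, spec)
  pn <- c(paste0("psi_", colnames(des@X)), paste0("p_", colnames(des@W)))
  dr <- matrix(0, nDraws, length(pn), dimnames = list(NULL, pn))
  for (nm in names(drawsOverride)) dr[, nm] <- drawsOverride[[nm]]
  post <- new("OccuPosterior", draws = dr,
              chain = rep(1:2, each = nDraws / 2), config = list(),
              acceptance = stats::setNames(rep(0.3, length(pn)), pn),
              scales = stats::setNames(rep(0.5, length(pn)), pn))
  pw <- pointwiseLogLik(post, des)
  new("OccuFit", spec = spec, design = des, det = sim$det, posterior = post,
      summary = occubayes:::.summarizeDraws(dr, post@chain),
      pointwise = pw, waic = waic(pw))
}

# brute-force two-term enumeration over the latent state
enumMarginal <- function(psi, p, y) {
  psi * prod(p^y * (1 - p)^(1 - y)) + (1 - psi) * as.numeric(all(y == 0))
}
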