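#' Define a synthetic winter wetland survey
#'
#' The scenario emulates the sampled study design: 33 wetlands (20 ACEP, 13
#' reference) of log-uniform size between 0.28 and 32.4 ha, a variable
#' number of point-count locations per wetland (1-9, mean about 4), two
#' survey years with two replicate visits per point per year, continuous
#' detection covariates drawn uniformly over their observed ranges, and
#' categorical vegetation covariates drawn with their observed proportions.
#' Detection histories are generated from the occupancy model itself
#' (`z ~ Bernoulli(psi)`, `y | z ~ Bernoulli(z * p)`), and per-wetland
#' richness from a Poisson log-linear model, so every ground-truth quantity
#' is known.
#'
#' Default species effects are on the encoded (standardized / dummy) scale.
#' They give each species a distinct, field-plausible profile: an abundant,
#' easily detected species avoiding dense 1x1 m shrub whose detectability
#' declines through the winter (`sosp`); a sparse species negatively
#' (`deju`) or positively (`swsp`) tied to wetland size with time-of-day
#' and wind detection effects; and a water-associated species (`wtsp`).
#'
#' @param nWetlands,nACEP total wetlands and how many are ACEP easements
#'   (default keeps the 20:13 ACEP:reference ratio).
#' @param nYears,nVisits survey years and replicate visits per year.
#' @param sizeRange wetland size range in ha (log-uniform draw).
#' @param meanPointsPerWetland mean of the 1-9 points-per-wetland
#'   distribution (`1 + Binomial(8, (m - 1) / 8)`).
#' @param speciesTruth named list per species with numeric vectors `alpha`
#'   (occupancy) and `beta` (detection), named by encoded design columns;
#'   unnamed columns are 0.
#' @param richnessCoefs named vector `intercept`, `type` (effect of the
#'   reference level), `size` (per SD of wetland size), `year` (effect of
#'   year 2) on the log scale.
#' @param seed integer seed.
#' @return list of class `simulationScenario`.
#' @export
simulationScenario <- function(nWetlands = 33, nACEP = round(nWetlands * 20 / 33),
                               nYears = 2,
                               nVisits = 2, sizeRange = c(0.28, 32.4),
                               meanPointsPerWetland = 4,
                               speciesTruth = NULL,
                               richnessCoefs = c(intercept = log(18),
                                                 type = -0.05, size = 0.2,
                                                 year = -0.08),
                               seed = 1) {
  if (is.null(speciesTruth))
    speciesTruth <- list(
      sosp = list(alpha = c("(Intercept)" = 2.2, typereference = -1.1,
                            size = 0.4, "shrub151-100" = -2.6),
                  beta = c("(Intercept)" = 0.9, day = -1.1)),
      swsp = list(alpha = c("(Intercept)" = -2.1, size = 2.4),
                  beta = c("(Intercept)" = 0.4, wind = -0.9)),
      deju = list(alpha = c("(Intercept)" = -1.4, size = -1.6),
                  beta = c("(Intercept)" = 0.3, time = 0.8)),
      wtsp = list(alpha = c("(Intercept)" = -0.5, waterpresent = 3.2),
                  beta = c("(Intercept)" = 0.5)))
  stopifnot(nACEP <= nWetlands, nYears >= 1, nVisits >= 1,
            meanPointsPerWetland >= 1, meanPointsPerWetland <= 9)
  structure(list(nWetlands = as.integer(nWetlands), nACEP = as.integer(nACEP),
                 nYears = as.integer(nYears), nVisits = as.integer(nVisits),
                 sizeRange = sizeRange,
                 meanPointsPerWetland = meanPointsPerWetland,
                 speciesTruth = speciesTruth, richnessCoefs = richnessCoefs,
                 seed = as.integer(seed)),
            class = "simulationScenario")
}

# categorical sampling proportions of the survey (vegetation and sky), and
# uniform ranges of the continuous detection covariates
.simProportions <- function() {
  list(herb = c(0.22, 0.26, 0.52), shrub1 = c(0.77, 0.23),
       bareground = c(0.73, 0.27), woody = c(0.87, 0.13),
       water = c(0.85, 0.15), shrub5 = c(0.41, 0.37, 0.22),
       sky = c(0.56, 0.44))
}

.simRanges <- function() {
  list(time = c(6.85, 15.22), wind = c(0, 4.5), temp = c(-12.2, 17.8),
       dist = c(0, 67), day = c(1, 102))
}

#' Simulate wetlands, points and covariate tables
#'
#' @param scenario a [simulationScenario()].
#' @param seed seed override (defaults to the scenario seed).
#' @return list with `wetlands` (wetland, type, size), `siteCovs` (one row
#'   per point x year) and `surveyCovs` (one row per point x year x visit),
#'   each passing the corresponding reader validations.
#' @export
simulateCovariates <- function(scenario = simulationScenario(),
                               seed = scenario$seed) {
  set.seed(seed)
  reg <- .covariateRegistry()
  prop <- .simProportions(); rng <- .simRanges()
  wet <- data.frame(
    wetland = sprintf("W%02d", seq_len(scenario$nWetlands)),
    type = rep(c("ACEP", "reference"),
               c(scenario$nACEP, scenario$nWetlands - scenario$nACEP)),
    size = exp(stats::runif(scenario$nWetlands, log(scenario$sizeRange[1]),
                            log(scenario$sizeRange[2]))),
    stringsAsFactors = FALSE)
  nPts <- 1L + stats::rbinom(scenario$nWetlands, 8L,
                             (scenario$meanPointsPerWetland - 1) / 8)
  pts <- data.frame(point = sprintf("P%03d", seq_len(sum(nPts))),
                    wetland = rep(wet$wetland, nPts),
                    stringsAsFactors = FALSE)
  years <- as.character(seq_len(scenario$nYears))
  sc <- expand.grid(point = pts$point, year = years,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sc <- sc[order(sc$point, sc$year), , drop = FALSE]
  wi <- match(pts$wetland[match(sc$point, pts$point)], wet$wetland)
  sc$wetland <- wet$wetland[wi]
  sc$type <- wet$type[wi]
  sc$size <- wet$size[wi]
  for (cv in c("herb", "shrub1", "bareground", "woody", "water", "shrub5"))
    sc[[cv]] <- sample(reg$occupancy[[cv]], nrow(sc), replace = TRUE,
                       prob = prop[[cv]])
  sc <- sc[c("point", "wetland", "year", "type", "size", "herb", "shrub1",
             "bareground", "woody", "water", "shrub5")]
  rownames(sc) <- NULL

  vc <- expand.grid(point = pts$point, year = years,
                    visit = seq_len(scenario$nVisits),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  vc <- vc[order(vc$point, vc$year, vc$visit), , drop = FALSE]
  nv <- nrow(vc)
  vc$time <- stats::runif(nv, rng$time[1], rng$time[2])
  vc$sky <- sample(reg$detection$sky, nv, replace = TRUE, prob = prop$sky)
  vc$wind <- stats::runif(nv, rng$wind[1], rng$wind[2])
  vc$temp <- stats::runif(nv, rng$temp[1], rng$temp[2])
  vc$dist <- stats::runif(nv, rng$dist[1], rng$dist[2])
  vc$day <- stats::runif(nv, rng$day[1], rng$day[2])
  rownames(vc) <- NULL
  list(wetlands = wet, siteCovs = sc, surveyCovs = vc)
}

# map a named truth vector onto encoded design columns (unnamed -> 0)
.truthVector <- function(truth, columns, what) {
  out <- stats::setNames(numeric(length(columns)), columns)
  bad <- setdiff(names(truth), columns)
  if (length(bad))
    .stopf("%s truth names not among design columns: %s", what,
           paste(bad, collapse = ", "))
  out[names(truth)] <- truth
  out
}

#' Simulate detection histories from known coefficients
#'
#' Draws the latent occupancy state `z_i ~ Bernoulli(invLogit(x_i alpha))`
#' for every site-unit, then visit outcomes
#' `y_ij ~ Bernoulli(z_i * invLogit(w_ij beta))`; unoccupied site-units
#' therefore have all-zero histories. The latent states are returned in a
#' side list for white-box testing and are never read by the fitting path.
#'
#' @param covs output of [simulateCovariates()].
#' @param alpha,beta named truth vectors over encoded design columns (all
#'   nine occupancy and six detection covariates are encoded; unnamed
#'   columns are 0).
#' @param species species label for the resulting table.
#' @param seed integer seed.
#' @return list with `det` (a [DetectionTable-class]), `z`, `psi` and `p`.
#' @export
simulateDetections <- function(covs, alpha, beta, species = "sosp",
                               seed = 1) {
  set.seed(seed)
  reg <- .covariateRegistry()
  sc <- covs$siteCovs
  encO <- .encodeCovariates(sc, names(reg$occupancy), "occupancy")
  a <- .truthVector(alpha, colnames(encO$M), "alpha")
  psi <- invLogit(drop(encO$M %*% a))
  n <- nrow(sc)
  z <- stats::rbinom(n, 1L, psi)

  vc <- covs$surveyCovs
  encD <- .encodeCovariates(vc, names(reg$detection), "detection")
  b <- .truthVector(beta, colnames(encD$M), "beta")
  p <- invLogit(drop(encD$M %*% b))
  skey <- paste(sc$point, sc$year, sep = "_")
  si <- match(paste(vc$point, vc$year, sep = "_"), skey)
  yv <- stats::rbinom(nrow(vc), 1L, z[si] * p)

  nVisits <- max(vc$visit)
  y <- matrix(NA_integer_, n, nVisits,
              dimnames = list(NULL, paste0("visit", seq_len(nVisits))))
  y[cbind(si, vc$visit)] <- yv
  det <- new("DetectionTable", species = species, siteId = skey,
             pointId = sc$point, wetlandId = sc$wetland,
             year = factor(sc$year, levels = c("1", "2")), y = y)
  list(det = det, z = z, psi = psi, p = p)
}

#' Simulate per-wetland apparent richness counts
#'
#' `richness ~ Poisson(exp(eta))` with
#' `eta = intercept + type * 1[reference] + size * sizeZ + year * 1[year 2]`,
#' wetland size standardized across the wetland-year rows.
#'
#' @param wetlands data.frame with `wetland`, `type`, `size`.
#' @param coefs named vector as in [simulationScenario()].
#' @param nYears number of survey years.
#' @param seed integer seed.
#' @return data.frame with `wetland`, `year`, `type`, `size`, `richness`.
#' @export
simulateRichness <- function(wetlands, coefs = c(intercept = log(18),
                                                 type = -0.05, size = 0.2,
                                                 year = -0.08),
                             nYears = 2, seed = 1) {
  set.seed(seed)
  rt <- expand.grid(wetland = wetlands$wetland,
                    year = as.character(seq_len(nYears)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rt <- rt[order(rt$wetland, rt$year), , drop = FALSE]
  wi <- match(rt$wetland, wetlands$wetland)
  rt$type <- wetlands$type[wi]
  rt$size <- wetlands$size[wi]
  sizeZ <- (rt$size - mean(rt$size)) / stats::sd(rt$size)
  eta <- coefs[["intercept"]] + coefs[["type"]] * (rt$type == "reference") +
    coefs[["size"]] * sizeZ + coefs[["year"]] * (rt$year == "2")
  rt$richness <- stats::rpois(nrow(rt), exp(eta))
  rt <- rt[c("wetland", "year", "type", "size", "richness")]
  rownames(rt) <- NULL
  rt
}

#' Simulate a complete synthetic study
#'
#' Covariates, detection histories for all four focal species, and the
#' richness table, all from one scenario and seed. The result can be
#' written to the four CSV dialects with [writeStudy()] and read back with
#' the `read*` functions.
#'
#' @param scenario a [simulationScenario()].
#' @param seed seed override (defaults to the scenario seed).
#' @return list with `scenario`, `wetlands`, `siteCovs`, `surveyCovs`,
#'   `detections` (named list of [DetectionTable-class]), `latent` (named
#'   list of true occupancy states), `truth` (the coefficient vectors) and
#'   `richness`.
#' @export
simulateStudy <- function(scenario = simulationScenario(),
                          seed = scenario$seed) {
  covs <- simulateCovariates(scenario, seed = seed)
  spp <- names(scenario$speciesTruth)
  dets <- vector("list", length(spp)); names(dets) <- spp
  latent <- dets
  for (i in seq_along(spp)) {
    tr <- scenario$speciesTruth[[spp[i]]]
    sim <- simulateDetections(covs, tr$alpha, tr$beta, species = spp[i],
                              seed = seed + 100L * i)
    dets[[i]] <- sim$det
    latent[[i]] <- sim$z
  }
  rich <- simulateRichness(covs$wetlands, scenario$richnessCoefs,
                           nYears = scenario$nYears, seed = seed + 999L)
  list(scenario = scenario, wetlands = covs$wetlands,
       siteCovs = covs$siteCovs, surveyCovs = covs$surveyCovs,
       detections = dets, latent = latent,
       truth = scenario$speciesTruth, richness = rich)
}
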