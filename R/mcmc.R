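#' Sampler configuration
#'
#' Defaults mirror the analysis settings: four chains of 10,000 iterations,
#' a 2,500-iteration burn-in (5,000 is used for the harder-mixing song and
#' swamp sparrow fits), and retention of every fifth post-burn-in sample.
#' Componentwise Gaussian random-walk proposals are scaled adaptively
#' during burn-in toward a target acceptance rate and frozen afterwards, so
#' the retained chains are Markov.
#'
#' @param nChains number of independent chains (>= 1).
#' @param nIterations iterations per chain.
#' @param nBurnin discarded initial iterations (< `nIterations`).
#' @param thin keep every `thin`-th post-burn-in sample (>= 1).
#' @param seed integer seed; chain `c` runs from `seed + c - 1`, making runs
#'   bit-reproducible.
#' @param proposalScale `"adaptive"` (default) or a fixed positive proposal
#'   SD.
#' @param targetAcceptance acceptance rate targeted during adaptation.
#' @param adaptBatch iterations per adaptation batch.
#' @return a validated list of class `mcmcConfig` with the derived
#'   `retainedPerChain = floor((nIterations - nBurnin) / thin)`.
#' @export
mcmcConfig <- function(nChains = 4, nIterations = 10000, nBurnin = 2500,
                       thin = 5, seed = 1, proposalScale = "adaptive",
                       targetAcceptance = 0.3, adaptBatch = 50) {
  nChains <- as.integer(nChains); nIterations <- as.integer(nIterations)
  nBurnin <- as.integer(nBurnin); thin <- as.integer(thin)
  if (nChains < 1L) .stopf("nChains must be >= 1")
  if (thin < 1L) .stopf("thin must be >= 1")
  if (nBurnin < 0L || nBurnin >= nIterations)
    .stopf("nBurnin must satisfy 0 <= nBurnin < nIterations")
  retained <- (nIterations - nBurnin) %/% thin
  if (retained < 1L)
    .stopf("no retained samples: floor((nIterations - nBurnin) / thin) = 0")
  if (!identical(proposalScale, "adaptive")) {
    proposalScale <- as.numeric(proposalScale)
    if (!is.finite(proposalScale) || proposalScale <= 0)
      .stopf("proposalScale must be 'adaptive' or a positive number")
  }
  structure(list(nChains = nChains, nIterations = nIterations,
                 nBurnin = nBurnin, thin = thin, seed = as.integer(seed),
                 proposalScale = proposalScale,
                 targetAcceptance = targetAcceptance,
                 adaptBatch = as.integer(adaptBatch),
                 retainedPerChain = retained),
            class = "mcmcConfig")
}

#' Log-density of the logistic(0, 1) prior
#'
#' All model coefficients carry independent standard logistic priors; a
#' logistic(0, 1) coefficient pushed through the inverse logit is exactly
#' Uniform(0, 1), i.e. the prior is flat on the probability scale for
#' intercept-only sub-models.
#'
#' @param params numeric vector of coefficients, or a list with elements
#'   `alpha` and `beta`.
#' @return sum of `log(exp(-x) / (1 + exp(-x))^2)` over all coefficients.
#' @examples
#' logPrior(0)  # log(1/4)
#' @export
logPrior <- function(params) {
  if (is.list(params)) params <- c(params$alpha, params$beta)
  sum(stats::dlogis(params, log = TRUE))
}

# One data-augmented Metropolis-within-Gibbs chain. Each iteration draws the
# latent occupancy states from their full conditional, then updates each
# coefficient with a Gaussian random-walk Metropolis step against the
# conditional (z-augmented) likelihood plus the logistic prior.
.occuChain <- function(design, config, chainSeed) {
  set.seed(chainSeed)
  X <- design@X; W <- design@W; vi <- design@visitIndex
  n <- nrow(X); Ka <- ncol(X); Kb <- ncol(W); K <- Ka + Kb
  yv <- vi$y; sv <- vi$site
  anyDet <- drop(rowsum(yv, sv)) > 0

  alpha <- numeric(Ka); beta <- numeric(Kb)
  etaX <- numeric(n); etaW <- numeric(length(yv))
  z <- ifelse(anyDet, 1L, stats::rbinom(n, 1L, 0.5))

  adaptive <- identical(config$proposalScale, "adaptive")
  scales <- rep(if (adaptive) 0.5 else config$proposalScale, K)
  out <- matrix(NA_real_, config$retainedPerChain, K)
  accBatch <- integer(K); batchCount <- 0L; batchNum <- 0L
  accKept <- integer(K)

  if (!is.finite(logLikelihood(list(alpha = alpha, beta = beta), design)))
    .stopf("non-finite posterior at initialization; re-initialize with different starting values")

  for (t in seq_len(config$nIterations)) {
    # latent state update (detection anywhere forces occupancy)
    lpsi  <- stats::plogis(etaX, log.p = TRUE)
    l1psi <- stats::plogis(etaX, log.p = TRUE, lower.tail = FALSE)
    lq <- stats::plogis(etaW, log.p = TRUE, lower.tail = FALSE)
    lnum <- lpsi + drop(rowsum(lq, sv))
    pz <- exp(lnum - .logAddExp(lnum, l1psi))
    z <- ifelse(anyDet, 1L, as.integer(stats::runif(n) < pz))

    # occupancy coefficients | z
    dataA <- sum(z * lpsi + (1 - z) * l1psi)
    for (k in seq_len(Ka)) {
      d <- stats::rnorm(1, 0, scales[k])
      etaXp <- etaX + X[, k] * d
      dataAp <- sum(z * stats::plogis(etaXp, log.p = TRUE) +
                    (1 - z) * stats::plogis(etaXp, log.p = TRUE, lower.tail = FALSE))
      lr <- dataAp - dataA +
        stats::dlogis(alpha[k] + d, log = TRUE) - stats::dlogis(alpha[k], log = TRUE)
      if (log(stats::runif(1)) < lr) {
        alpha[k] <- alpha[k] + d; etaX <- etaXp; dataA <- dataAp
        accBatch[k] <- accBatch[k] + 1L
        if (t > config$nBurnin) accKept[k] <- accKept[k] + 1L
      }
    }

    # detection coefficients | z: only visits at occupied site-units count
    ov <- z[sv] == 1L
    yo <- yv[ov]
    eo <- etaW[ov]
    dataB <- sum(yo * stats::plogis(eo, log.p = TRUE) +
                 (1 - yo) * stats::plogis(eo, log.p = TRUE, lower.tail = FALSE))
    for (k in seq_len(Kb)) {
      d <- stats::rnorm(1, 0, scales[Ka + k])
      etaWp <- etaW + W[, k] * d
      eo <- etaWp[ov]
      dataBp <- sum(yo * stats::plogis(eo, log.p = TRUE) +
                    (1 - yo) * stats::plogis(eo, log.p = TRUE, lower.tail = FALSE))
      lr <- dataBp - dataB +
        stats::dlogis(beta[k] + d, log = TRUE) - stats::dlogis(beta[k], log = TRUE)
      if (log(stats::runif(1)) < lr) {
        beta[k] <- beta[k] + d; etaW <- etaWp; dataB <- dataBp
        accBatch[Ka + k] <- accBatch[Ka + k] + 1L
        if (t > config$nBurnin) accKept[Ka + k] <- accKept[Ka + k] + 1L
      }
    }

    # adaptive proposal scaling, burn-in only; frozen afterwards
    batchCount <- batchCount + 1L
    if (adaptive && t <= config$nBurnin && batchCount == config$adaptBatch) {
      batchNum <- batchNum + 1L
      rate <- accBatch / config$adaptBatch
      delta <- min(0.1, 1 / sqrt(batchNum))
      scales <- scales * exp(ifelse(rate > config$targetAcceptance, delta, -delta))
      accBatch <- integer(K); batchCount <- 0L
    } else if (batchCount == config$adaptBatch) {
      accBatch <- integer(K); batchCount <- 0L
    }

    if (t > config$nBurnin && (t - config$nBurnin) %% config$thin == 0L) {
      kp <- (t - config$nBurnin) %/% config$thin
      if (kp <= nrow(out)) out[kp, ] <- c(alpha, beta)
    }
  }
  list(draws = out, acceptance = accKept / (config$nIterations - config$nBurnin),
       scales = scales)
}

#' Sample the posterior of an occupancy model
#'
#' Runs `nChains` independent data-augmented Metropolis-within-Gibbs chains:
#' each iteration (a) Gibbs-draws every latent occupancy state from its full
#' conditional ([conditionalZProbability()]), then (b) updates each
#' occupancy coefficient against the Bernoulli occupancy likelihood of the
#' augmented states, and each detection coefficient against the visit
#' likelihood at currently occupied site-units, both under logistic(0, 1)
#' priors. Burn-in is discarded and thinning applied; the run is fully
#' reproducible given the config seed.
#'
#' @param design an [OccuDesign-class].
#' @param config an [mcmcConfig()].
#' @return an [OccuPosterior-class] with
#'   `nChains * floor((nIterations - nBurnin) / thin)` retained draws.
#' @export
runChains <- function(design, config = mcmcConfig()) {
  stopifnot(is(design, "OccuDesign"), inherits(config, "mcmcConfig"))
  pn <- c(paste0("psi_", colnames(design@X)), paste0("p_", colnames(design@W)))
  res <- lapply(seq_len(config$nChains), function(ch)
    .occuChain(design, config, chainSeed = config$seed + ch - 1L))
  dr <- do.call(rbind, lapply(res, `[[`, "draws"))
  colnames(dr) <- pn
  acc <- colMeans(do.call(rbind, lapply(res, `[[`, "acceptance")))
  sc <- colMeans(do.call(rbind, lapply(res, `[[`, "scales")))
  names(acc) <- names(sc) <- pn
  new("OccuPosterior", draws = dr,
      chain = rep(seq_len(config$nChains), each = config$retainedPerChain),
      config = unclass(config), acceptance = acc, scales = sc)
}

#' Sample coefficients from the prior alone
#'
#' Runs the same componentwise random-walk machinery with the likelihood
#' switched off, so the target is the logistic(0, 1) prior itself. Used to
#' calibrate the sampler: prior draws pushed through [invLogit()] must be
#' Uniform(0, 1).
#'
#' @param config an [mcmcConfig()].
#' @param nCoef number of independent coefficients to sample.
#' @return an [OccuPosterior-class].
#' @export
samplePrior <- function(config = mcmcConfig(), nCoef = 1) {
  stopifnot(inherits(config, "mcmcConfig"))
  K <- as.integer(nCoef)
  runOne <- function(chainSeed) {
    set.seed(chainSeed)
    theta <- numeric(K)
    adaptive <- identical(config$proposalScale, "adaptive")
    scales <- rep(if (adaptive) 0.5 else config$proposalScale, K)
    out <- matrix(NA_real_, config$retainedPerChain, K)
    accBatch <- integer(K); batchCount <- 0L; batchNum <- 0L
    accKept <- integer(K)
    for (t in seq_len(config$nIterations)) {
      for (k in seq_len(K)) {
        d <- stats::rnorm(1, 0, scales[k])
        lr <- stats::dlogis(theta[k] + d, log = TRUE) -
              stats::dlogis(theta[k], log = TRUE)
        if (log(stats::runif(1)) < lr) {
          theta[k] <- theta[k] + d
          accBatch[k] <- accBatch[k] + 1L
          if (t > config$nBurnin) accKept[k] <- accKept[k] + 1L
        }
      }
      batchCount <- batchCount + 1L
      if (adaptive && t <= config$nBurnin && batchCount == config$adaptBatch) {
        batchNum <- batchNum + 1L
        delta <- min(0.1, 1 / sqrt(batchNum))
        scales <- scales * exp(ifelse(accBatch / config$adaptBatch >
                                      config$targetAcceptance, delta, -delta))
        accBatch <- integer(K); batchCount <- 0L
      } else if (batchCount == config$adaptBatch) {
        accBatch <- integer(K); batchCount <- 0L
      }
      if (t > config$nBurnin && (t - config$nBurnin) %% config$thin == 0L)
        out[(t - config$nBurnin) %/% config$thin, ] <- theta
    }
    list(draws = out, acceptance = accKept / (config$nIterations - config$nBurnin),
         scales = scales)
  }
  res <- lapply(seq_len(config$nChains), function(ch) runOne(config$seed + ch - 1L))
  dr <- do.call(rbind, lapply(res, `[[`, "draws"))
  colnames(dr) <- paste0("coef", seq_len(K))
  acc <- colMeans(do.call(rbind, lapply(res, `[[`, "acceptance")))
  sc <- colMeans(do.call(rbind, lapply(res, `[[`, "scales")))
  names(acc) <- names(sc) <- colnames(dr)
  new("OccuPosterior", draws = dr,
      chain = rep(seq_len(config$nChains), each = config$retainedPerChain),
      config = unclass(config), acceptance = acc, scales = sc)
}
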