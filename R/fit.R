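#' Fit a single-species Bayesian occupancy model
#'
#' End-to-end fit: builds the design matrices for the given specification,
#' samples the posterior with the data-augmented Metropolis-within-Gibbs
#' sampler, and attaches posterior summaries (with split-chain R-hat), the
#' pointwise integrated log-likelihood matrix and its WAIC.
#'
#' @param det a [DetectionTable-class].
#' @param siteCovs site-covariate data.frame ([readSiteCovariates()]).
#' @param surveyCovs per-visit covariate data.frame
#'   ([readSurveyCovariates()]).
#' @param spec a [ModelSpec-class]; defaults to the global model with every
#'   measured covariate.
#' @param config an [mcmcConfig()].
#' @return an [OccuFit-class].
#' @examples
#' \donttest{
#' study <- simulateStudy(simulationScenario(seed = 7))
#' fit <- fitOccupancy(study$detections$sosp, study$siteCovs,
#'                     study$surveyCovs,
#'                     modelSpec("sosp", "size", "day"),
#'                     mcmcConfig(nChains = 2, nIterations = 1500,
#'                                nBurnin = 500, seed = 7))
#' summarizePosterior(fit)
#' }
#' @export
fitOccupancy <- function(det, siteCovs, surveyCovs,
                         spec = globalModelSpec(det@species),
                         config = mcmcConfig()) {
  design <- buildDesign(det, siteCovs, surveyCovs, spec)
  post <- runChains(design, config)
  pw <- pointwiseLogLik(post, design)
  new("OccuFit", spec = spec, design = design, det = det, posterior = post,
      summary = .summarizeDraws(post@draws, post@chain),
      pointwise = pw, waic = waic(pw))
}
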