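#' @import methods
NULL

#' Model specification for a single-species occupancy model
#'
#' A `ModelSpec` names the species and the occupancy- and detection-level
#' covariates entering the two logistic-linear sub-models. Intercepts are
#' always included implicitly and never listed.
#'
#' @slot species single character, one of `"sosp"`, `"swsp"`, `"deju"`,
#'   `"wtsp"` (song sparrow, swamp sparrow, dark-eyed junco, white-throated
#'   sparrow) or any other label carried through unchanged.
#' @slot occupancy character vector of occupancy covariate names.
#' @slot detection character vector of detection covariate names.
#' @seealso [modelSpec()], [globalModelSpec()]
#' @export
setClass("ModelSpec",
  slots = c(species = "character", occupancy = "character",
            detection = "character"))

setValidity("ModelSpec", function(object) {
  reg <- .covariateRegistry()
  msgs <- character()
  if (length(object@species) != 1L) msgs <- c(msgs, "species must be a single label")
  badO <- setdiff(object@occupancy, names(reg$occupancy))
  if (length(badO)) msgs <- c(msgs, paste0("unknown occupancy covariate(s): ",
                                           paste(badO, collapse = ", ")))
  badD <- setdiff(object@detection, names(reg$detection))
  if (length(badD)) msgs <- c(msgs, paste0("unknown detection covariate(s): ",
                                           paste(badD, collapse = ", ")))
  if (anyDuplicated(object@occupancy)) msgs <- c(msgs, "duplicated occupancy covariate")
  if (anyDuplicated(object@detection)) msgs <- c(msgs, "duplicated detection covariate")
  if (length(msgs)) msgs else TRUE
})

#' Replicated detection/non-detection histories
#'
#' One row per site-unit (a point-count location in one survey year, the
#' closure unit of the single-season model) holding the ordered binary
#' outcomes of the replicate visits. Missing visits are `NA` and are dropped
#' from the likelihood, never imputed.
#'
#' @slot species character label for the species the histories refer to.
#' @slot siteId character, unique site-unit identifier (point x year).
#' @slot pointId character, point-count location identifier.
#' @slot wetlandId character, wetland the point belongs to.
#' @slot year factor with levels `"1"` and `"2"`.
#' @slot y integer matrix, site-units x visits, entries 0, 1 or `NA`.
#' @seealso [readDetectionTable()], [simulateDetections()]
#' @export
setClass("DetectionTable",
  slots = c(species = "character", siteId = "character", pointId = "character",
            wetlandId = "character", year = "factor", y = "matrix"))

setValidity("DetectionTable", function(object) {
  msgs <- character()
  n <- length(object@siteId)
  if (nrow(object@y) != n || length(object@pointId) != n ||
      length(object@wetlandId) != n || length(object@year) != n)
    msgs <- c(msgs, "slot lengths disagree")
  v <- object@y[!is.na(object@y)]
  if (!all(v %in% c(0, 1)))
    msgs <- c(msgs, "detection entries must be 0, 1 or NA")
  if (n > 0 && any(rowSums(!is.na(object@y)) < 1L))
    msgs <- c(msgs, "every site-unit needs at least one non-missing visit")
  if (anyDuplicated(object@siteId)) msgs <- c(msgs, "duplicated site-unit id")
  # a point belongs to exactly one wetland
  mp <- tapply(object@wetlandId, object@pointId, function(w) length(unique(w)))
  if (n > 0 && any(mp > 1L))
    msgs <- c(msgs, "a point maps to more than one wetland")
  if (length(msgs)) msgs else TRUE
})

#' Encoded design matrices for the two sub-models
#'
#' Holds the occupancy design matrix `X` (one row per site-unit) and the
#' detection design matrix `W` (one row per realized, non-missing visit),
#' together with the encoding record (dummy reference levels, means and SDs
#' used for z-standardization) that makes the encoding reproducible and
#' invertible.
#'
#' @slot X numeric matrix, site-units x occupancy coefficients (intercept
#'   first).
#' @slot W numeric matrix, realized visits x detection coefficients.
#' @slot visitIndex data.frame with columns `site` (row of `X`), `visit`
#'   (replicate index) and `y` (the 0/1 outcome) for each row of `W`.
#' @slot encoding list with elements `occupancy` and `detection`; each is a
#'   per-covariate record (`type`, and `mean`/`sd` or `levels`/`reference`).
#' @slot xBlocks,wBlocks named lists mapping each covariate to the design
#'   columns it owns (categorical covariates own one column per non-reference
#'   level and are always kept or dropped as a block).
#' @slot siteCovs data.frame of the raw site covariates in site-unit order
#'   (kept for covariate profiles and odds-ratio reference points).
#' @slot spec the [ModelSpec-class] the design was built for.
#' @seealso [buildDesign()]
#' @export
setClass("OccuDesign",
  slots = c(X = "matrix", W = "matrix", visitIndex = "data.frame",
            encoding = "list", xBlocks = "list", wBlocks = "list",
            siteCovs = "data.frame", spec = "ModelSpec"))

setValidity("OccuDesign", function(object) {
  msgs <- character()
  if (nrow(object@W) != nrow(object@visitIndex))
    msgs <- c(msgs, "W and visitIndex row counts disagree")
  if (anyNA(object@X) || anyNA(object@W))
    msgs <- c(msgs, "design matrices must not contain missing values")
  if (nrow(object@visitIndex) > 0 &&
      (max(object@visitIndex$site) > nrow(object@X) || min(object@visitIndex$site) < 1L))
    msgs <- c(msgs, "visitIndex refers to site-units outside X")
  if (length(msgs)) msgs else TRUE
})

#' Retained posterior draws from multiple Markov chains
#'
#' Post-burn-in, thinned coefficient draws, labeled by chain. Row count is
#' always `nChains * floor((nIterations - nBurnin) / thin)`.
#'
#' @slot draws numeric matrix, retained samples x parameters; column names
#'   are `psi_*` for occupancy and `p_*` for detection coefficients.
#' @slot chain integer vector giving the chain of each draw.
#' @slot config the [mcmcConfig()] list the sampler ran with.
#' @slot acceptance named numeric, per-coefficient acceptance rate over the
#'   retained (post-adaptation) phase, averaged across chains.
#' @slot scales named numeric, final random-walk proposal SDs (averaged
#'   across chains; frozen at the end of burn-in so retained chains are
#'   Markov).
#' @seealso [runChains()], [summarizePosterior()], [gelmanRhat()]
#' @export
setClass("OccuPosterior",
  slots = c(draws = "matrix", chain = "integer", config = "list",
            acceptance = "numeric", scales = "numeric"))

setValidity("OccuPosterior", function(object) {
  msgs <- character()
  if (nrow(object@draws) != length(object@chain))
    msgs <- c(msgs, "draws and chain labels disagree")
  if (anyNA(object@draws) || any(!is.finite(object@draws)))
    msgs <- c(msgs, "draws must be finite")
  if (length(msgs)) msgs else TRUE
})

#' WAIC decomposition
#'
#' The widely applicable information criterion computed from the pointwise
#' posterior log-likelihood matrix: `waic = -2 * (lppd - pWAIC)` with the
#' variance-form penalty.
#'
#' @slot lppd log pointwise predictive density, summed over site-units.
#' @slot pWAIC effective-parameter penalty (sum of across-draw variances of
#'   the pointwise log-likelihood).
#' @slot waic the criterion value.
#' @slot pointwise data.frame with per-site-unit `lppd` and `pWAIC`
#'   contributions.
#' @seealso [waic()]
#' @export
setClass("WAICResult",
  slots = c(lppd = "numeric", pWAIC = "numeric", waic = "numeric",
            pointwise = "data.frame"))

setValidity("WAICResult", function(object) {
  msgs <- character()
  if (object@pWAIC < -1e-8) msgs <- c(msgs, "pWAIC must be nonnegative")
  if (abs(object@waic - (-2 * (object@lppd - object@pWAIC))) > 1e-8)
    msgs <- c(msgs, "waic must equal -2 * (lppd - pWAIC)")
  if (length(msgs)) msgs else TRUE
})

#' A fitted single-species occupancy model
#'
#' Bundles the data, design, posterior draws, posterior summaries with
#' split-chain R-hat, the pointwise log-likelihood matrix and its WAIC.
#'
#' @slot spec the [ModelSpec-class] that was fit.
#' @slot design the [OccuDesign-class] used.
#' @slot det the [DetectionTable-class] used.
#' @slot posterior the [OccuPosterior-class] draws.
#' @slot summary data.frame of per-parameter posterior mean, median, 50% and
#'   95% equal-tailed credible intervals and R-hat.
#' @slot pointwise numeric matrix (draws x site-units) of integrated
#'   site-unit log-likelihoods (latent occupancy state marginalized out).
#' @slot waic the [WAICResult-class] for this fit.
#' @seealso [fitOccupancy()]
#' @export
setClass("OccuFit",
  slots = c(spec = "ModelSpec", design = "OccuDesign", det = "DetectionTable",
            posterior = "OccuPosterior", summary = "data.frame",
            pointwise = "matrix", waic = "WAICResult"))
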