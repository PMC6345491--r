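#' Build occupancy and detection design matrices
#'
#' Encodes the covariates named by a [ModelSpec-class] into the occupancy
#' design matrix `X` (one row per site-unit, intercept first) and the
#' detection design matrix `W` (one row per realized, non-missing visit).
#' Continuous covariates are z-standardized with the sample mean and SD of
#' the rows entering each matrix; categorical covariates are dummy-coded
#' against the first registry level. All transforms are stored in the
#' encoding record, so re-applying the record to the raw tables reproduces
#' the matrices exactly.
#'
#' @param det a [DetectionTable-class].
#' @param siteCovs site-covariate data.frame (one row per point x year; see
#'   [readSiteCovariates()]).
#' @param surveyCovs per-visit covariate data.frame (see
#'   [readSurveyCovariates()]).
#' @param spec a [ModelSpec-class].
#' @param encoding optional encoding record from a previous build, to be
#'   re-applied instead of recomputed.
#' @return an [OccuDesign-class].
#' @export
buildDesign <- function(det, siteCovs, surveyCovs, spec, encoding = NULL) {
  stopifnot(is(det, "DetectionTable"), is(spec, "ModelSpec"))
  key <- paste(siteCovs$point, siteCovs$year, sep = "_")
  idx <- match(det@siteId, key)
  if (anyNA(idx))
    .stopf("site covariates missing for site-unit(s): %s",
           paste(utils::head(det@siteId[is.na(idx)], 3), collapse = ", "))
  sc <- siteCovs[idx, , drop = FALSE]
  rownames(sc) <- NULL

  # realized visits only: missing visits are dropped from W and from the
  # detection likelihood
  obs <- which(!is.na(det@y), arr.ind = TRUE)
  obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
  visitIndex <- data.frame(site = as.integer(obs[, 1]),
                           visit = as.integer(obs[, 2]),
                           y = as.integer(det@y[obs]))
  vkey <- paste(surveyCovs$point, surveyCovs$year, surveyCovs$visit, sep = "_")
  want <- paste(det@pointId[visitIndex$site], det@year[visitIndex$site],
                visitIndex$visit, sep = "_")
  vidx <- match(want, vkey)
  if (anyNA(vidx))
    .stopf("survey covariates missing for visit(s): %s",
           paste(utils::head(want[is.na(vidx)], 3), collapse = ", "))
  vc <- surveyCovs[vidx, , drop = FALSE]

  encO <- .encodeCovariates(sc, spec@occupancy, "occupancy",
                            encoding = encoding$occupancy)
  encD <- .encodeCovariates(vc, spec@detection, "detection",
                            encoding = encoding$detection)
  new("OccuDesign", X = encO$M, W = encD$M, visitIndex = visitIndex,
      encoding = list(occupancy = encO$encoding, detection = encD$encoding),
      xBlocks = encO$blocks, wBlocks = encD$blocks,
      siteCovs = sc, spec = spec)
}
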