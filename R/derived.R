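#' Posterior occupancy probability at a covariate profile
#'
#' Evaluates `psi = invLogit(x %*% alpha)` for every retained draw at a
#' covariate profile: named covariates are fixed at the requested values
#' and every unspecified covariate is held at its sample mean — for
#' categorical covariates, the design-column means of the dummies (the
#' "average site"). Continuous values are supplied on the raw scale and
#' standardized through the stored encoding record.
#'
#' @param fit an [OccuFit-class].
#' @param profile named list, e.g. `list(type = "ACEP", size = 5)`.
#' @return list with `mean`, `median`, `lower`, `upper` (95% equal-tailed)
#'   and the resolved design row `x`.
#' @export
occupancyAtProfile <- function(fit, profile = list()) {
  stopifnot(is(fit, "OccuFit"))
  enc <- fit@design@encoding$occupancy
  x <- colMeans(fit@design@X)
  for (nm in names(profile)) {
    e <- enc[[nm]]
    if (is.null(e))
      .stopf("covariate '%s' is not in the occupancy sub-model", nm)
    if (e$type == "continuous") {
      x[nm] <- (as.numeric(profile[[nm]]) - e$mean) / e$sd
    } else {
      lev <- as.character(profile[[nm]])
      if (!lev %in% e$levels)
        .stopf("'%s' is not a level of '%s' (allowed: %s)", lev, nm,
               paste(e$levels, collapse = ", "))
      cols <- fit@design@xBlocks[[nm]]
      x[cols] <- as.numeric(cols == paste0(nm, lev))
    }
  }
  Ka <- ncol(fit@design@X)
  psi <- invLogit(drop(draws(fit)[, seq_len(Ka), drop = FALSE] %*% x))
  ci <- .etInterval(psi, 0.95)
  list(mean = mean(psi), median = stats::median(psi),
       lower = ci[1], upper = ci[2], x = x)
}

#' Posterior log-odds-ratio curve against a continuous covariate
#'
#' For each grid value `s` of a continuous occupancy covariate, the log
#' odds ratio of occupancy relative to a reference value is linear in every
#' draw: `LOR(s) = alpha_cov * (z(s) - z(ref))` on the standardized scale,
#' so the curve passes through 0 with a zero-width band at the reference.
#' The default reference is the sample median of the covariate.
#'
#' @param fit an [OccuFit-class].
#' @param covariate continuous occupancy covariate name (default `"size"`).
#' @param grid covariate values (raw scale); default 50 points spanning the
#'   observed range.
#' @param reference `"median"` (default), `"mean"`, or a number on the raw
#'   scale.
#' @return data.frame with columns `value`, `lor` (posterior mean), `lower`
#'   and `upper` (95% equal-tailed band); the reference value is attached
#'   as attribute `"reference"`.
#' @export
oddsRatioCurve <- function(fit, covariate = "size", grid = NULL,
                           reference = "median") {
  stopifnot(is(fit, "OccuFit"))
  e <- fit@design@encoding$occupancy[[covariate]]
  if (is.null(e))
    .stopf("covariate '%s' is not in the occupancy sub-model", covariate)
  if (e$type != "continuous")
    .stopf("covariate '%s' is not continuous", covariate)
  raw <- fit@design@siteCovs[[covariate]]
  ref <- if (identical(reference, "median")) stats::median(raw)
         else if (identical(reference, "mean")) mean(raw)
         else as.numeric(reference)
  if (is.null(grid))
    grid <- seq(min(raw), max(raw), length.out = 50)
  a <- draws(fit)[, paste0("psi_", covariate)]
  dz <- (grid - ref) / e$sd
  lor <- outer(a, dz)             # draws x grid
  qs <- apply(lor, 2, .etInterval, level = 0.95)
  out <- data.frame(value = grid, lor = colMeans(lor),
                    lower = qs[1, ], upper = qs[2, ])
  attr(out, "reference") <- ref
  out
}
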