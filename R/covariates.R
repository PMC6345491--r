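# Covariate registry: names, roles and level sets of the survey design.
# Categorical covariates list their levels in order; the first level is the
# dummy-coding reference. "continuous" covariates are z-standardized.
.covariateRegistry <- function() {
  list(
    occupancy = list(
      type       = c("ACEP", "reference"),
      year       = c("1", "2"),
      size       = "continuous",
      herb       = c("0-25", "26-75", "76-100"),
      shrub1     = c("0-50", "51-100"),
      bareground = c("0-50", "51-100"),
      woody      = c("absent", "present"),
      water      = c("absent", "present"),
      shrub5     = c("0-25", "26-75", "76-100")
    ),
    detection = list(
      time = "continuous",
      sky  = c("0-1", "2-3"),
      wind = "continuous",
      temp = "continuous",
      dist = "continuous",
      day  = "continuous"
    )
  )
}

#' @describeIn modelSpec constructor: `x` is the species label; occupancy
#'   covariates may be any of `type`, `year`, `size`, `herb`, `shrub1`,
#'   `bareground`, `woody`, `water`, `shrub5`; detection covariates any of
#'   `time`, `sky`, `wind`, `temp`, `dist`, `day`. Intercepts are implicit.
#' @param occupancy,detection covariate name vectors (constructor only).
#' @export
setMethod("modelSpec", "character",
  function(x, occupancy = character(), detection = character(), ...) {
    new("ModelSpec", species = x,
        occupancy = as.character(occupancy),
        detection = as.character(detection))
  })

#' The global model: every measured covariate in both sub-models
#'
#' @param species species label.
#' @return a [ModelSpec-class] with all nine occupancy and all six detection
#'   covariates (19 coefficient columns including both intercepts).
#' @export
globalModelSpec <- function(species) {
  reg <- .covariateRegistry()
  modelSpec(species, occupancy = names(reg$occupancy),
            detection = names(reg$detection))
}

# Encode covariates into a design matrix with intercept. When `encoding` is
# supplied the stored means/SDs and level sets are re-applied verbatim, so
# encoding is reproducible and invertible.
.encodeCovariates <- function(df, covs, role, encoding = NULL) {
  reg <- .covariateRegistry()[[role]]
  n <- nrow(df)
  cols <- list("(Intercept)" = rep(1, n))
  blocks <- list()
  enc <- list()
  for (cv in covs) {
    if (!cv %in% names(reg))
      .stopf("unknown %s covariate '%s'", role, cv)
    if (!cv %in% names(df))
      .stopf("covariate '%s' is missing from the table", cv)
    x <- df[[cv]]
    if (anyNA(x))
      .stopf("covariate '%s' contains missing values", cv)
    info <- reg[[cv]]
    if (identical(info, "continuous")) {
      x <- as.numeric(x)
      if (is.null(encoding)) {
        m <- mean(x); s <- stats::sd(x)
        if (!is.finite(s) || s == 0)
          .stopf("continuous covariate '%s' has zero variance", cv)
      } else {
        m <- encoding[[cv]]$mean; s <- encoding[[cv]]$sd
      }
      enc[[cv]] <- list(type = "continuous", mean = m, sd = s)
      cols[[cv]] <- (x - m) / s
      blocks[[cv]] <- cv
    } else {
      lev <- info
      x <- as.character(x)
      bad <- which(!x %in% lev)
      if (length(bad))
        .stopf("covariate '%s' has unknown level '%s' (row %d); allowed: %s",
               cv, x[bad[1]], bad[1], paste(lev, collapse = ", "))
      enc[[cv]] <- list(type = "categorical", levels = lev, reference = lev[1])
      nm <- paste0(cv, lev[-1])
      for (k in seq_along(nm))
        cols[[nm[k]]] <- as.numeric(x == lev[-1][k])
      blocks[[cv]] <- nm
    }
  }
  M <- do.call(cbind, cols)
  colnames(M) <- names(cols)
  list(M = M, encoding = enc, blocks = blocks)
}

#' Pairwise collinearity screen for occupancy covariates
#'
#' Computes the absolute Pearson correlation between every pair of
#' covariates (categorical covariates via their numeric level codes) and
#' flags pairs at or above the threshold. The screen mirrors the common
#' pre-modeling check that all pairwise `|r| < 0.5`. Pairs involving a
#' constant column have undefined correlation and are reported as `NA`,
#' not flagged.
#'
#' @param siteCovs site-covariate data.frame (one row per site-unit).
#' @param covariates covariate names to screen; defaults to every occupancy
#'   covariate present in `siteCovs`.
#' @param threshold absolute-correlation flag threshold (default 0.5).
#' @return data.frame with columns `cov1`, `cov2`, `r` (absolute
#'   correlation) and `flagged`.
#' @export
checkCollinearity <- function(siteCovs, covariates = NULL, threshold = 0.5) {
  reg <- .covariateRegistry()$occupancy
  if (is.null(covariates))
    covariates <- intersect(names(reg), names(siteCovs))
  if (length(covariates) < 2L)
    .stopf("need at least two covariates to screen")
  if (nrow(siteCovs) < 3L)
    .stopf("need at least three rows to estimate correlations")
  num <- lapply(covariates, function(cv) {
    x <- siteCovs[[cv]]
    if (is.null(x)) .stopf("covariate '%s' is missing from the table", cv)
    if (cv %in% names(reg) && !identical(reg[[cv]], "continuous"))
      as.numeric(factor(as.character(x), levels = reg[[cv]]))
    else as.numeric(x)
  })
  names(num) <- covariates
  pairs <- utils::combn(covariates, 2)
  r <- apply(pairs, 2, function(pr) {
    a <- num[[pr[1]]]; b <- num[[pr[2]]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    abs(stats::cor(a, b))
  })
  data.frame(cov1 = pairs[1, ], cov2 = pairs[2, ], r = r,
             flagged = !is.na(r) & r >= threshold,
             stringsAsFactors = FALSE)
}
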