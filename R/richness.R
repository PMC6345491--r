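#' Apparent species richness per wetland-year
#'
#' Counts distinct species detected at each wetland in each year (the
#' wetland, not the point count, is the replication unit). Richness is
#' apparent: it is not corrected for detection probability.
#'
#' @param detections long data.frame with columns `wetland`, `year`,
#'   `species`; duplicate records of a species at a wetland-year count once.
#' @param wetlands optional data.frame with columns `wetland`, `year` (and
#'   any of `type`, `size`, carried through). Wetland-years listed here but
#'   absent from `detections` get richness 0.
#' @return data.frame with one row per wetland-year: `wetland`, `year`,
#'   `richness`, plus `type`/`size` when supplied.
#' @export
computeApparentRichness <- function(detections, wetlands = NULL) {
  stopifnot(all(c("wetland", "year", "species") %in% names(detections)))
  dd <- unique(detections[c("wetland", "year", "species")])
  agg <- stats::aggregate(species ~ wetland + year, data = dd, FUN = length)
  names(agg)[3] <- "richness"
  if (!is.null(wetlands)) {
    out <- merge(wetlands, agg, by = c("wetland", "year"), all.x = TRUE)
    out$richness[is.na(out$richness)] <- 0L
  } else out <- agg
  out$richness <- as.integer(out$richness)
  out[order(out$wetland, out$year), , drop = FALSE]
}

#' Poisson log-linear model of apparent species richness
#'
#' Fits `richness ~ type + size + year` with a log link by iteratively
#' reweighted least squares (via [stats::glm()]), treating the wetland-year
#' as the replication unit. Wetland size enters z-standardized (the
#' mean/SD used are returned in `encoding`), so its coefficient is the log
#' proportional change in expected richness per SD of wetland size; `type`
#' is coded against the ACEP reference and `year` against year 1. Wald z
#' statistics and two-sided normal-approximation p-values accompany each
#' coefficient.
#'
#' @param richnessTable data.frame with columns `richness` (nonnegative
#'   integer) and whichever of `type`, `size`, `year` the model uses.
#' @param covariates subset of `c("type", "size", "year")`; empty fits an
#'   intercept-only model.
#' @return list of class `richnessGLM`: `coefficients` (data.frame with
#'   `term`, `estimate`, `se`, `z`, `p`), `deviance`, `fitted`, `encoding`,
#'   and the underlying `glm` object.
#' @examples
#' rt <- data.frame(richness = c(1, 2, 3))
#' fitRichnessGLM(rt, covariates = character())$coefficients  # log(2)
#' @export
fitRichnessGLM <- function(richnessTable,
                           covariates = c("type", "size", "year")) {
  rt <- as.data.frame(richnessTable)
  if (!"richness" %in% names(rt)) .stopf("richnessTable needs a 'richness' column")
  r <- rt$richness
  if (any(!is.finite(r) | r < 0 | r != round(r)))
    .stopf("richness must be nonnegative integers")
  if (length(covariates))
    covariates <- match.arg(covariates, c("type", "size", "year"),
                            several.ok = TRUE)
  if (length(setdiff(covariates, names(rt))))
    .stopf("missing covariate column(s): %s",
           paste(setdiff(covariates, names(rt)), collapse = ", "))
  df <- data.frame(richness = as.integer(r))
  encoding <- list()
  if ("type" %in% covariates)
    df$type <- factor(as.character(rt$type), levels = c("ACEP", "reference"))
  if ("year" %in% covariates)
    df$year <- factor(as.character(rt$year))
  if ("size" %in% covariates) {
    m <- mean(rt$size); s <- stats::sd(rt$size)
    if (!is.finite(s) || s == 0) .stopf("size has zero variance")
    encoding$size <- list(mean = m, sd = s)
    df$size <- (rt$size - m) / s
  }
  form <- stats::reformulate(if (length(covariates)) covariates else "1",
                             response = "richness")
  mm <- stats::model.matrix(form, df)
  if (nrow(mm) <= ncol(mm))
    .stopf("need more rows (%d) than coefficients (%d)", nrow(mm), ncol(mm))
  if (qr(mm)$rank < ncol(mm))
    .stopf("design is rank-deficient (aliased covariates)")
  fit <- stats::glm(form, family = stats::poisson(), data = df,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged)
    .stopf("IRLS did not converge in %d iterations (deviance %.6g)",
           fit$iter, fit$deviance)
  cf <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], z = cf[, 3], p = cf[, 4],
                              stringsAsFactors = FALSE, row.names = NULL),
    deviance = fit$deviance,
    fitted = as.numeric(stats::fitted(fit)),
    encoding = encoding,
    glm = fit), class = "richnessGLM")
}

#' @export
print.richnessGLM <- function(x, ...) {
  cat("Poisson richness model (log link)\n")
  print(x$coefficients, digits = 3)
  cat(sprintf("Residual deviance: %.2f on %d rows\n", x$deviance,
              length(x$fitted)))
  invisible(x)
}

#' One-page text report of a richness fit
#'
#' @param x a `richnessGLM`.
#' @return character vector of report lines.
#' @export
formatRichnessReport <- function(x) {
  cf <- x$coefficients
  c("Apparent species richness ~ Poisson(log link)",
    sprintf("  rows (wetland-years): %d; residual deviance %.2f",
            length(x$fitted), x$deviance),
    sprintf("  %-14s log-change %7.3f  se %6.3f  z %6.2f  p %s",
            cf$term, cf$estimate, cf$se, cf$z,
            ifelse(cf$p < 0.01, "<0.01", sprintf("%.2f", cf$p))))
}
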