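.speciesCodes <- c("sosp", "swsp", "deju", "wtsp")

.readCSV <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.requireColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .stopf("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
}

.warnExtraColumns <- function(df, known, path) {
  extra <- setdiff(names(df), known)
  if (length(extra))
    message(sprintf("%s: ignoring unknown column(s): %s",
                    path, paste(extra, collapse = ", ")))
}

.coerceDetection <- function(x, col, path) {
  out <- rep(NA_integer_, length(x))
  chr <- trimws(as.character(x))
  blank <- is.na(x) | chr == ""
  ok <- blank | chr %in% c("0", "1")
  if (!all(ok))
    .stopf("%s: column '%s' row %d has value '%s'; expected 0, 1 or blank",
           path, col, which(!ok)[1], chr[which(!ok)[1]])
  out[!blank] <- as.integer(chr[!blank])
  out
}

#' Read a detection/non-detection table for one species
#'
#' Reads the replicate-survey dialect: one row per point-count location per
#' year, columns `point`, `wetland`, `year`, and two replicate-survey
#' columns per species (`sosp1`, `sosp2`, ..., `wtsp2`). Blank cells are
#' missing visits. Each point x year row becomes one site-unit with two
#' ordered visit entries.
#'
#' @param path CSV file path.
#' @param species one of `"sosp"`, `"swsp"`, `"deju"`, `"wtsp"`.
#' @return a [DetectionTable-class].
#' @export
readDetectionTable <- function(path, species) {
  species <- match.arg(species, .speciesCodes)
  df <- .readCSV(path)
  vcols <- paste0(species, 1:2)
  .requireColumns(df, c("point", "wetland", "year", vcols), path)
  known <- c("point", "wetland", "year",
             as.vector(outer(.speciesCodes, 1:2, paste0)))
  .warnExtraColumns(df, known, path)
  y <- cbind(.coerceDetection(df[[vcols[1]]], vcols[1], path),
             .coerceDetection(df[[vcols[2]]], vcols[2], path))
  colnames(y) <- c("visit1", "visit2")
  yr <- factor(as.character(df$year), levels = c("1", "2"))
  if (anyNA(yr)) .stopf("%s: year must be 1 or 2", path)
  new("DetectionTable", species = species,
      siteId = paste(df$point, df$year, sep = "_"),
      pointId = as.character(df$point),
      wetlandId = as.character(df$wetland),
      year = yr, y = y)
}

#' Read the per-site-unit occupancy covariate table
#'
#' Columns: `point`, `year`, `type` (ACEP/reference), `size` (ha, > 0) and
#' the categorical vegetation covariates `herb`, `shrub1`, `bareground`,
#' `woody`, `water`, `shrub5`; an optional `wetland` column is carried
#' through. One row per point x year.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
readSiteCovariates <- function(path) {
  df <- .readCSV(path)
  need <- c("point", "year", "type", "size", "herb", "shrub1",
            "bareground", "woody", "water", "shrub5")
  .requireColumns(df, need, path)
  .warnExtraColumns(df, c(need, "wetland"), path)
  df$point <- as.character(df$point)
  df$year <- as.character(df$year)
  validateSiteCovariates(df)
  df
}

#' @rdname readSiteCovariates
#' @param df a site-covariate data.frame to validate in place.
#' @export
validateSiteCovariates <- function(df) {
  reg <- .covariateRegistry()$occupancy
  if (anyDuplicated(df[c("point", "year")]))
    .stopf("site covariates: more than one row per point x year")
  if (any(!is.finite(df$size)) || any(df$size <= 0))
    .stopf("site covariates: size must be positive")
  for (cv in c("type", "year", "herb", "shrub1", "bareground", "woody",
               "water", "shrub5")) {
    lev <- reg[[cv]]
    bad <- which(!as.character(df[[cv]]) %in% lev)
    if (length(bad))
      .stopf("site covariates: '%s' row %d has level '%s'; allowed: %s",
             cv, bad[1], as.character(df[[cv]])[bad[1]],
             paste(lev, collapse = ", "))
  }
  invisible(df)
}

#' Read the per-visit detection covariate table
#'
#' Columns: `point`, `year`, `visit` (1 or 2), `time` (hours, 0-24), `sky`
#' (`0-1` clear to partly cloudy, `2-3` overcast to light precipitation),
#' `wind` (m/s, >= 0), `temp` (deg C), `dist` (ambient noise, dB), `day`
#' (day of survey season, 1 = first survey day). One row per
#' point x year x visit.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
readSurveyCovariates <- function(path) {
  df <- .readCSV(path)
  need <- c("point", "year", "visit", "time", "sky", "wind", "temp",
            "dist", "day")
  .requireColumns(df, need, path)
  .warnExtraColumns(df, need, path)
  df$point <- as.character(df$point)
  df$year <- as.character(df$year)
  df$visit <- as.integer(df$visit)
  validateSurveyCovariates(df)
  df
}

#' @rdname readSurveyCovariates
#' @param df a survey-covariate data.frame to validate in place.
#' @export
validateSurveyCovariates <- function(df) {
  if (anyDuplicated(df[c("point", "year", "visit")]))
    .stopf("survey covariates: more than one row per point x year x visit")
  if (any(df$wind < 0)) .stopf("survey covariates: wind must be >= 0")
  if (any(df$time < 0 | df$time > 24))
    .stopf("survey covariates: time must be within [0, 24]")
  sky <- .covariateRegistry()$detection$sky
  bad <- which(!as.character(df$sky) %in% sky)
  if (length(bad))
    .stopf("survey covariates: 'sky' row %d has level '%s'; allowed: %s",
           bad[1], as.character(df$sky)[bad[1]], paste(sky, collapse = ", "))
  invisible(df)
}

#' Read the per-wetland apparent species richness table
#'
#' Columns: `wetland`, `year`, `type`, `size`, `richness` (nonnegative
#' integer count of distinct species). One row per wetland x year.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
readRichnessTable <- function(path) {
  df <- .readCSV(path)
  need <- c("wetland", "year", "type", "size", "richness")
  .requireColumns(df, need, path)
  .warnExtraColumns(df, need, path)
  df$wetland <- as.character(df$wetland)
  df$year <- as.character(df$year)
  rich <- as.numeric(df$richness)
  bad <- which(!is.finite(rich) | rich < 0 | rich != round(rich))
  if (length(bad))
    .stopf("%s: richness row %d is '%s'; expected a nonnegative integer",
           path, bad[1], as.character(df$richness)[bad[1]])
  df$richness <- as.integer(round(rich))
  if (anyDuplicated(df[c("wetland", "year")]))
    .stopf("%s: more than one row per wetland x year", path)
  badT <- which(!df$type %in% c("ACEP", "reference"))
  if (length(badT))
    .stopf("%s: type row %d must be ACEP or reference", path, badT[1])
  df
}

#' Write the four survey CSV dialects of a simulated study
#'
#' Serializes a [simulateStudy()] result to `s1_detections.csv`,
#' `s2_site_covariates.csv`, `s3_survey_covariates.csv` and
#' `s4_richness.csv` in `dir`, in exactly the dialects the readers parse,
#' so a written study round-trips cell-for-cell.
#'
#' @param study a list as returned by [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the four file paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d1 <- study$detections[[1]]
  det <- data.frame(point = d1@pointId, wetland = d1@wetlandId,
                    year = as.character(d1@year), stringsAsFactors = FALSE)
  for (sp in names(study$detections)) {
    y <- study$detections[[sp]]@y
    det[[paste0(sp, 1)]] <- y[, 1]
    det[[paste0(sp, 2)]] <- y[, 2]
  }
  paths <- file.path(dir, c("s1_detections.csv", "s2_site_covariates.csv",
                            "s3_survey_covariates.csv", "s4_richness.csv"))
  utils::write.csv(det, paths[1], row.names = FALSE, na = "")
  utils::write.csv(study$siteCovs, paths[2], row.names = FALSE, na = "")
  utils::write.csv(study$surveyCovs, paths[3], row.names = FALSE, na = "")
  utils::write.csv(study$richness, paths[4], row.names = FALSE, na = "")
  invisible(paths)
}

#' Export retained posterior draws to CSV
#'
#' One row per retained sample with `chain`, `sample` and one column per
#' coefficient.
#'
#' @param posterior an [OccuPosterior-class] or [OccuFit-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeDraws <- function(posterior, path) {
  if (is(posterior, "OccuFit")) posterior <- posterior@posterior
  df <- data.frame(chain = posterior@chain,
                   sample = stats::ave(posterior@chain, posterior@chain,
                                       FUN = seq_along))
  df <- cbind(df, as.data.frame(posterior@draws))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
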