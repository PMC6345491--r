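#' Reduce a global model by the 50% credible-interval rule
#'
#' Builds the reduced specification from a fitted global model by dropping
#' every covariate whose coefficients all have 50% credible intervals
#' overlapping 0. A covariate is retained iff at least one of its
#' coefficients (a categorical covariate owns one dummy column per
#' non-reference level and is kept or dropped as a whole block) has a 50%
#' interval excluding 0. The rule is applied separately to the occupancy
#' and detection covariate lists; intercepts are always retained. Reduction
#' is idempotent: reducing a reduced model with its own fit changes nothing
#' beyond sampling variability of the intervals.
#'
#' @param fit an [OccuFit-class] of the model to reduce (typically the
#'   global model).
#' @param spec the [ModelSpec-class] to reduce; defaults to the fit's own.
#' @return the reduced [ModelSpec-class].
#' @export
reduceModel <- function(fit, spec = modelSpec(fit)) {
  stopifnot(is(fit, "OccuFit"), is(spec, "ModelSpec"))
  sm <- fit@summary
  excludesZero <- function(parNames) {
    rows <- sm[match(parNames, sm$parameter), , drop = FALSE]
    if (anyNA(rows$parameter))
      .stopf("fit lacks coefficients for: %s",
             paste(parNames[is.na(rows$parameter)], collapse = ", "))
    any(rows$lower50 > 0 | rows$upper50 < 0)
  }
  keepO <- vapply(spec@occupancy, function(cv)
    excludesZero(paste0("psi_", fit@design@xBlocks[[cv]])), logical(1))
  keepD <- vapply(spec@detection, function(cv)
    excludesZero(paste0("p_", fit@design@wBlocks[[cv]])), logical(1))
  modelSpec(spec@species, occupancy = spec@occupancy[keepO],
            detection = spec@detection[keepD])
}

.comparisonEntry <- function(x, name) {
  if (is(x, "OccuFit")) {
    list(name = name, waic = x@waic@waic,
         K = ncol(x@design@X) + ncol(x@design@W),
         siteIds = sort(x@det@siteId),
         occupancy = paste(x@spec@occupancy, collapse = " + "),
         detection = paste(x@spec@detection, collapse = " + "))
  } else if (is.list(x) && !is.null(x$waic) && !is.null(x$K)) {
    w <- if (is(x$waic, "WAICResult")) x$waic@waic else as.numeric(x$waic)
    list(name = name, waic = w, K = as.integer(x$K),
         siteIds = x$siteIds, occupancy = NA_character_,
         detection = NA_character_)
  } else .stopf("compareModels entries must be OccuFit or list(waic=, K=)")
}

#' Compare fitted models by WAIC
#'
#' Tabulates WAIC and the difference from the best (lowest-WAIC) model.
#' Ties are broken toward the model with fewer coefficient columns `K`
#' (intercepts included). Models must have been fit to the same site-unit
#' set.
#'
#' @param fits named list of [OccuFit-class] objects, or of lists with
#'   elements `waic` (a [WAICResult-class] or number) and `K`.
#' @return data.frame ordered by WAIC with columns `model`, `occupancy`,
#'   `detection`, `K`, `WAIC`, `dWAIC` and `best`.
#' @export
compareModels <- function(fits) {
  if (length(fits) < 1L) .stopf("compareModels needs at least one model")
  nms <- names(fits)
  if (is.null(nms)) nms <- paste0("model", seq_along(fits))
  entries <- Map(.comparisonEntry, fits, nms)
  ids <- Filter(Negate(is.null), lapply(entries, `[[`, "siteIds"))
  if (length(ids) > 1L && !all(vapply(ids[-1], identical, logical(1), ids[[1]])))
    .stopf("models were fit to different site-unit sets")
  tab <- data.frame(model = vapply(entries, `[[`, character(1), "name"),
                    occupancy = vapply(entries, `[[`, character(1), "occupancy"),
                    detection = vapply(entries, `[[`, character(1), "detection"),
                    K = vapply(entries, function(e) as.integer(e$K), integer(1)),
                    WAIC = vapply(entries, `[[`, numeric(1), "waic"),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(tab$WAIC, tab$K), , drop = FALSE]
  tab$dWAIC <- tab$WAIC - tab$WAIC[1]
  tab$best <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  tab
}

#' Render a model-comparison table as text
#'
#' @param tab output of [compareModels()].
#' @return character vector of lines (also printed invisibly usable with
#'   `writeLines`).
#' @export
formatComparison <- function(tab) {
  lines <- c(sprintf("%-16s %4s %10s %8s", "Model", "K", "WAIC", "dWAIC"))
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines, sprintf("%-16s %4d %10.1f %8.2f", tab$model[i],
                              tab$K[i], tab$WAIC[i], tab$dWAIC[i]))
    if (!is.na(tab$occupancy[i]))
      lines <- c(lines,
                 sprintf("    occupancy: %s", ifelse(tab$occupancy[i] == "",
                         "(intercept only)", tab$occupancy[i])),
                 sprintf("    detection: %s", ifelse(tab$detection[i] == "",
                         "(intercept only)", tab$detection[i])))
  }
  lines
}
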