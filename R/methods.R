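#' @describeIn draws retained draws of a posterior
#' @export
setMethod("draws", "OccuPosterior", function(x) x@draws)

#' @describeIn draws retained draws of a fitted model
#' @export
setMethod("draws", "OccuFit", function(x) x@posterior@draws)

#' @describeIn chainIds chain labels of a posterior
#' @export
setMethod("chainIds", "OccuPosterior", function(x) x@chain)

#' @describeIn chainIds chain labels of a fitted model
#' @export
setMethod("chainIds", "OccuFit", function(x) x@posterior@chain)

#' @describeIn naiveOccupancy fraction of site-units with >= 1 detection
#' @export
setMethod("naiveOccupancy", "DetectionTable", function(x) {
  mean(rowSums(x@y == 1, na.rm = TRUE) > 0)
})

#' @describeIn nSiteUnits site-units in a detection table
#' @export
setMethod("nSiteUnits", "DetectionTable", function(x) nrow(x@y))

#' @describeIn nSiteUnits site-units in a design
#' @export
setMethod("nSiteUnits", "OccuDesign", function(x) nrow(x@X))

#' @describeIn nSiteUnits site-units in a fit
#' @export
setMethod("nSiteUnits", "OccuFit", function(x) nrow(x@design@X))

#' @describeIn modelSpec specification of a design
#' @export
setMethod("modelSpec", "OccuDesign", function(x) x@spec)

#' @describeIn modelSpec specification of a fit
#' @export
setMethod("modelSpec", "OccuFit", function(x) x@spec)

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec for species '", object@species, "'\n", sep = "")
  cat("  occupancy: ", if (length(object@occupancy))
    paste(object@occupancy, collapse = ", ") else "(intercept only)", "\n", sep = "")
  cat("  detection: ", if (length(object@detection))
    paste(object@detection, collapse = ", ") else "(intercept only)", "\n", sep = "")
})

setMethod("show", "DetectionTable", function(object) {
  cat("DetectionTable ('", object@species, "'): ", nrow(object@y),
      " site-units (", length(unique(object@pointId)), " points, ",
      length(unique(object@wetlandId)), " wetlands), ",
      ncol(object@y), " visits\n", sep = "")
  cat(sprintf("  naive occupancy: %.3f; missing visits: %d\n",
              naiveOccupancy(object), sum(is.na(object@y))))
})

setMethod("show", "OccuDesign", function(object) {
  cat("OccuDesign: X ", nrow(object@X), " x ", ncol(object@X),
      ", W ", nrow(object@W), " x ", ncol(object@W), "\n", sep = "")
  cat("  occupancy columns: ", paste(colnames(object@X), collapse = ", "), "\n",
      sep = "")
  cat("  detection columns: ", paste(colnames(object@W), collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "OccuPosterior", function(object) {
  nc <- length(unique(object@chain))
  cat("OccuPosterior: ", nrow(object@draws), " retained draws (",
      nc, " chains), ", ncol(object@draws), " parameters\n", sep = "")
  cat(sprintf("  mean acceptance rate: %.2f\n", mean(object@acceptance)))
})

setMethod("show", "WAICResult", function(object) {
  cat(sprintf("WAIC = %.2f  (lppd = %.2f, pWAIC = %.2f, %d site-units)\n",
              object@waic, object@lppd, object@pWAIC, nrow(object@pointwise)))
})

setMethod("show", "OccuFit", function(object) {
  cat("OccuFit for species '", object@spec@species, "' (",
      nSiteUnits(object), " site-units)\n", sep = "")
  show(object@spec)
  cat(sprintf("  WAIC %.2f; max R-hat %.3f\n", object@waic@waic,
              suppressWarnings(max(object@summary$rhat, na.rm = TRUE))))
  print(utils::head(object@summary, 12), digits = 3)
  if (nrow(object@summary) > 12) cat("  ...\n")
})
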