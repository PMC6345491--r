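#' Extract retained posterior draws
#'
#' @param x an [OccuPosterior-class] or [OccuFit-class].
#' @return numeric matrix, retained samples x parameters.
#' @export
setGeneric("draws", function(x) standardGeneric("draws"))

#' Chain label of each retained draw
#'
#' @param x an [OccuPosterior-class] or [OccuFit-class].
#' @return integer vector.
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' Widely applicable information criterion
#'
#' For a pointwise log-likelihood matrix (draws x site-units) computes
#' `lppd = sum_i log mean_s exp(ll[s, i])` with a stable log-mean-exp,
#' the variance-form penalty `pWAIC = sum_i var_s(ll[s, i])` (sample
#' variance, denominator S - 1), and `waic = -2 * (lppd - pWAIC)`. For an
#' [OccuFit-class] returns the stored result.
#'
#' @param x matrix of pointwise log-likelihoods or an [OccuFit-class].
#' @param ... unused.
#' @return a [WAICResult-class].
#' @examples
#' pw <- matrix(log(c(0.5, 0.5, 0.25, 0.75)), nrow = 2)
#' waic(pw)
#' @export
setGeneric("waic", function(x, ...) standardGeneric("waic"))

#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' Classic potential scale reduction factor (no rank normalization): each
#' chain is split in half, and R-hat is `sqrt(varPlus / W)` where `W` is the
#' mean within-chain variance and `varPlus = (n - 1) / n * W + B / n` mixes
#' in the between-chain variance `B`. Values near 1 indicate between-chain
#' agreement; parameters with zero within-chain variance are reported as
#' `NA`.
#'
#' @param x an [OccuPosterior-class] or [OccuFit-class]; needs at least two
#'   chains and four retained samples per chain.
#' @param ... unused.
#' @return named numeric vector of R-hat values, one per parameter.
#' @export
setGeneric("gelmanRhat", function(x, ...) standardGeneric("gelmanRhat"))

#' Posterior summaries with credible intervals
#'
#' Per-parameter posterior mean, median, and equal-tailed 50% and 95%
#' credible intervals. Interval endpoints are empirical quantiles with
#' linear interpolation of order statistics (type 7), stated explicitly so
#' downstream decisions (the 50%-interval covariate-reduction rule) are
#' reproducible.
#'
#' @param x an [OccuPosterior-class] or [OccuFit-class].
#' @param ... unused.
#' @return data.frame with columns `parameter`, `mean`, `median`, `lower50`,
#'   `upper50`, `lower95`, `upper95` (and `rhat` when computable).
#' @export
setGeneric("summarizePosterior", function(x, ...) standardGeneric("summarizePosterior"))

#' Naive occupancy
#'
#' Fraction of site-units with at least one detection; a lower bound on the
#' occupancy probability under imperfect detection.
#'
#' @param x a [DetectionTable-class].
#' @return numeric scalar in \[0, 1\].
#' @export
setGeneric("naiveOccupancy", function(x) standardGeneric("naiveOccupancy"))

#' Number of site-units
#'
#' @param x a [DetectionTable-class], [OccuDesign-class] or [OccuFit-class].
#' @return integer.
#' @export
setGeneric("nSiteUnits", function(x) standardGeneric("nSiteUnits"))

#' Build or extract a model specification
#'
#' Called with a species label, builds a [ModelSpec-class] from covariate
#' name vectors; called on an [OccuFit-class] or [OccuDesign-class],
#' extracts the specification the object was built with.
#'
#' @param x species label (character) or an object carrying a spec.
#' @param ... for the constructor: `occupancy` and `detection` covariate
#'   name vectors.
#' @return a [ModelSpec-class].
#' @examples
#' modelSpec("deju", occupancy = c("size", "shrub5"),
#'           detection = c("time", "sky", "wind", "temp", "dist"))
#' @export
setGeneric("modelSpec", function(x, ...) standardGeneric("modelSpec"))
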