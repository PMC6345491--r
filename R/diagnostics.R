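.splitRhatOne <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[length(v) - h + seq_len(h)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @describeIn gelmanRhat split R-hat of a posterior
#' @export
setMethod("gelmanRhat", "OccuPosterior", function(x, ...) {
  nPer <- table(x@chain)
  if (length(nPer) < 2L) .stopf("gelmanRhat needs at least two chains")
  if (min(nPer) < 4L) .stopf("gelmanRhat needs at least 4 retained samples per chain")
  out <- apply(x@draws, 2, .splitRhatOne, chain = x@chain)
  names(out) <- colnames(x@draws)
  out
})

#' @describeIn gelmanRhat split R-hat of a fitted model
#' @export
setMethod("gelmanRhat", "OccuFit", function(x, ...) gelmanRhat(x@posterior))

.summarizeDraws <- function(dr, chain = NULL) {
  q <- t(apply(dr, 2, stats::quantile,
               probs = c(0.025, 0.25, 0.75, 0.975), names = FALSE, type = 7))
  out <- data.frame(parameter = colnames(dr),
                    mean = colMeans(dr),
                    median = apply(dr, 2, stats::median),
                    lower50 = q[, 2], upper50 = q[, 3],
                    lower95 = q[, 1], upper95 = q[, 4],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(chain)) {
    nPer <- table(chain)
    if (length(nPer) >= 2L && min(nPer) >= 4L)
      out$rhat <- apply(dr, 2, .splitRhatOne, chain = chain)
  }
  out
}

#' @describeIn summarizePosterior summaries of a posterior
#' @export
setMethod("summarizePosterior", "OccuPosterior", function(x, ...) {
  if (nrow(x@draws) == 0L) .stopf("posterior contains no draws")
  .summarizeDraws(x@draws, x@chain)
})

#' @describeIn summarizePosterior stored summaries of a fit
#' @export
setMethod("summarizePosterior", "OccuFit", function(x, ...) x@summary)
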