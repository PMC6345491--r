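#' @describeIn waic compute WAIC from a pointwise log-likelihood matrix
#' @export
setMethod("waic", "matrix", function(x, ...) {
  if (nrow(x) < 2L)
    .stopf("waic needs at least two draws (the penalty is a variance)")
  lppd_i <- apply(x, 2, .logMeanExp)
  p_i <- apply(x, 2, stats::var)
  lppd <- sum(lppd_i); pW <- sum(p_i)
  new("WAICResult", lppd = lppd, pWAIC = pW, waic = -2 * (lppd - pW),
      pointwise = data.frame(lppd = lppd_i, pWAIC = p_i))
})

#' @describeIn waic stored WAIC of a fitted model
#' @export
setMethod("waic", "OccuFit", function(x, ...) x@waic)
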