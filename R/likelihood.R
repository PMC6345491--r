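#' Integrated site-unit likelihood under imperfect detection
#'
#' The single-season occupancy model assumes a latent occupancy state
#' `z ~ Bernoulli(psi)` and, conditional on `z`, visit outcomes
#' `y_j ~ Bernoulli(z * p_j)`. Marginalizing `z` gives the two-term site
#' likelihood
#' `psi * prod_j p_j^y_j (1 - p_j)^(1 - y_j) + (1 - psi) * 1[all y_j = 0]`.
#' Computation is in log space with a stable two-term log-sum-exp.
#'
#' @param psi occupancy probability in (0, 1).
#' @param p vector of per-visit detection probabilities in (0, 1).
#' @param y binary detection history (missing visits already removed).
#' @return the marginal likelihood, in (0, 1].
#' @examples
#' siteMarginalLikelihood(0.5, c(0.5, 0.5), c(0, 0))  # 0.625
#' siteMarginalLikelihood(0.5, c(0.5, 0.5), c(1, 0))  # 0.125
#' @export
siteMarginalLikelihood <- function(psi, p, y) {
  exp(.siteMarginalLogLik(psi, p, y))
}

.siteMarginalLogLik <- function(psi, p, y) {
  if (length(p) != length(y)) .stopf("p and y lengths differ")
  if (!all(y %in% c(0, 1))) .stopf("y must contain only 0 and 1")
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  if (any(y == 1)) log(psi) + ll
  else .logAddExp(log(psi) + ll, log1p(-psi))
}

#' Conditional probability that a site-unit is occupied
#'
#' Full conditional of the latent occupancy state given the detection
#' history: 1 whenever any visit detected the species, otherwise
#' `psi * prod_j (1 - p_j) / (psi * prod_j (1 - p_j) + 1 - psi)`. This is
#' the Gibbs update used inside the sampler.
#'
#' @inheritParams siteMarginalLikelihood
#' @return probability in \[0, 1\].
#' @examples
#' conditionalZProbability(0.5, c(0.5, 0.5), c(0, 0))  # 0.2
#' conditionalZProbability(0.5, c(0.5, 0.5), c(1, 0))  # 1
#' @export
conditionalZProbability <- function(psi, p, y) {
  if (length(p) != length(y)) .stopf("p and y lengths differ")
  if (!all(y %in% c(0, 1))) .stopf("y must contain only 0 and 1")
  if (any(y == 1)) return(1)
  lnum <- log(psi) + sum(log1p(-p))
  exp(lnum - .logAddExp(lnum, log1p(-psi)))
}

# Vectorized per-site-unit integrated log-likelihood for one coefficient
# vector pair. Returns length-n vector.
.pointwiseLogLikOnce <- function(alpha, beta, design) {
  etaX <- drop(design@X %*% alpha)
  etaW <- drop(design@W %*% beta)
  vi <- design@visitIndex
  lp  <- stats::plogis(etaW, log.p = TRUE)
  lq  <- stats::plogis(etaW, log.p = TRUE, lower.tail = FALSE)
  perSite <- drop(rowsum(vi$y * lp + (1 - vi$y) * lq, vi$site))
  anyDet <- drop(rowsum(vi$y, vi$site)) > 0
  lpsi  <- stats::plogis(etaX, log.p = TRUE)
  l1psi <- stats::plogis(etaX, log.p = TRUE, lower.tail = FALSE)
  out <- .logAddExp(lpsi + perSite, l1psi)
  out[anyDet] <- (lpsi + perSite)[anyDet]
  out
}

#' Joint log-likelihood of an occupancy model
#'
#' Sum over site-units of the integrated (latent state marginalized)
#' site log-likelihood.
#'
#' @param params list with elements `alpha` (occupancy coefficients, length
#'   `ncol(X)`) and `beta` (detection coefficients, length `ncol(W)`), both
#'   on the logit scale.
#' @param design an [OccuDesign-class] (carries the detection outcomes of
#'   the realized visits).
#' @return finite numeric scalar.
#' @export
logLikelihood <- function(params, design) {
  stopifnot(is(design, "OccuDesign"))
  if (length(params$alpha) != ncol(design@X))
    .stopf("alpha length %d does not match %d occupancy columns",
           length(params$alpha), ncol(design@X))
  if (length(params$beta) != ncol(design@W))
    .stopf("beta length %d does not match %d detection columns",
           length(params$beta), ncol(design@W))
  sum(.pointwiseLogLikOnce(params$alpha, params$beta, design))
}

#' Pointwise log-likelihood matrix across posterior draws
#'
#' Entry `(s, i)` is the integrated log-likelihood of site-unit `i` at draw
#' `s`; this matrix is the input to [waic()]. The pointwise unit is the
#' site-unit marginal (latent state integrated out), not per-visit terms.
#'
#' @param posterior an [OccuPosterior-class].
#' @param design the [OccuDesign-class] the posterior was sampled under.
#' @return numeric matrix, draws x site-units.
#' @export
pointwiseLogLik <- function(posterior, design) {
  stopifnot(is(posterior, "OccuPosterior"))
  dr <- posterior@draws
  if (nrow(dr) == 0L) .stopf("posterior contains no draws")
  Ka <- ncol(design@X)
  Kb <- ncol(design@W)
  if (ncol(dr) != Ka + Kb)
    .stopf("posterior has %d parameters; design needs %d", ncol(dr), Ka + Kb)
  out <- matrix(NA_real_, nrow(dr), nrow(design@X))
  for (s in seq_len(nrow(dr)))
    out[s, ] <- .pointwiseLogLikOnce(dr[s, seq_len(Ka)],
                                     dr[s, Ka + seq_len(Kb)], design)
  out
}
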