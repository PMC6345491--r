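#' Inverse-logit link
#'
#' Numerically stable logistic function `1 / (1 + exp(-x))`; saturates to 0
#' and 1 for large `|x|` without overflow.
#'
#' @param x numeric vector on the log-odds scale.
#' @return probabilities in (0, 1).
#' @examples
#' invLogit(0)          # 0.5
#' invLogit(40)         # 1 to within 1e-12
#' @export
invLogit <- function(x) stats::plogis(x)

# pairwise log(exp(a) + exp(b)), vectorized and -Inf safe
.logAddExp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log(mean(exp(x))) without overflow
.logMeanExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# equal-tailed interval endpoints, type-7 quantiles
.etInterval <- function(x, level) {
  stats::quantile(x, probs = c((1 - level) / 2, (1 + level) / 2),
                  names = FALSE, type = 7)
}
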