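#' Negative binomial log probability mass function
#'
#' Log-density of the NB distribution in its mean/dispersion
#' parameterisation, \deqn{\Pr(X=x) = \frac{\Gamma(r+x)}{x!\,\Gamma(r)}
#' \left(\frac{r}{r+m}\right)^r \left(\frac{m}{r+m}\right)^x,} where
#' `m` is the mean and `r` the dispersion (shape) parameter, so that
#' \eqn{\mathrm{Var}(X) = m + m^2/r}.  Small `r` means strong
#' overdispersion; as \eqn{r \to \infty} the distribution approaches
#' the Poisson with mean `m`.
#'
#' All computation is done on the log scale via [lgamma()]; raw
#' factorials are never formed, so large counts are safe.
#'
#' @param x Vector of non-negative integer counts.
#' @param m Mean parameter, positive. Recycled against `x`.
#' @param r Dispersion parameter, positive. Recycled against `x`.
#' @return Numeric vector of log-probabilities.
#' @examples
#' nb_log_pmf(0:3, m = 1, r = 1) # geometric(1/2): log(1/2), log(1/4), ...
#' @export
nb_log_pmf <- function(x, m, r) {
  check_counts(x, "x")
  check_positive(m, "m")
  check_positive(r, "r")
  lgamma(r + x) - lgamma(r) - lgamma(x + 1) +
    r * (log(r) - log(r + m)) + x * (log(m) - log(r + m))
}

#' Zero-inflated negative binomial log probability mass function
#'
#' Log-density of the ZINB mixture: with probability `p_zero` the count
#' is a structural zero, otherwise it is drawn from an NB distribution
#' with mean `m` and dispersion `r`:
#' \deqn{\Pr(Y=0) = p + (1-p)\left(1 + m/r\right)^{-r}, \qquad
#'       \Pr(Y=y) = (1-p)\,\mathrm{NB}(y; m, r), \; y \ge 1.}
#' The zero branch is evaluated with a log-sum-exp so that tiny mixing
#' weights or tiny NB zero masses do not underflow.
#'
#' @param y Vector of non-negative integer counts.
#' @param p_zero Structural-zero probability in `[0, 1]`.
#' @param m NB mean parameter, positive.
#' @param r NB dispersion parameter, positive.
#' @return Numeric vector of log-probabilities.
#' @examples
#' zinb_log_pmf(0, p_zero = 0.5, m = 1, r = 1) # log(0.75)
#' @export
zinb_log_pmf <- function(y, p_zero, m, r) {
  check_counts(y, "y")
  check_positive(m, "m")
  check_positive(r, "r")
  if (any(!is.finite(p_zero)) || any(p_zero < 0) || any(p_zero > 1)) {
    stop("`p_zero` must lie in [0, 1].", call. = FALSE)
  }
  n <- max(length(y), length(p_zero), length(m), length(r))
  y <- rep_len(y, n); p_zero <- rep_len(p_zero, n)
  m <- rep_len(m, n); r <- rep_len(r, n)
  out <- log1p(-p_zero) + nb_log_pmf(y, m, r)
  zero <- y == 0
  if (any(zero)) {
    lnb0 <- -r[zero] * log1p(m[zero] / r[zero]) # NB mass at zero, log scale
    out[zero] <- log_sum_exp2(log(p_zero[zero]), log1p(-p_zero[zero]) + lnb0)
  }
  out
}

#' Mean and variance of the zero-inflated negative binomial
#'
#' Closed-form moments of the ZINB mixture: \eqn{E(Y) = (1-p)m} and
#' \eqn{\mathrm{Var}(Y) = m(1-p)\bigl(1 + m(p + 1/r)\bigr)}.
#'
#' @inheritParams zinb_log_pmf
#' @return A named list with elements `mean` and `variance`.
#' @examples
#' zinb_moments(p_zero = 0.5, m = 1, r = 1) # mean 0.5, variance 1.25
#' @export
zinb_moments <- function(p_zero, m, r) {
  check_positive(m, "m")
  check_positive(r, "r")
  if (any(!is.finite(p_zero)) || any(p_zero < 0) || any(p_zero > 1)) {
    stop("`p_zero` must lie in [0, 1].", call. = FALSE)
  }
  list(
    mean = (1 - p_zero) * m,
    variance = m * (1 - p_zero) * (1 + m * (p_zero + 1 / r))
  )
}

# Elementwise log(exp(a) + exp(b)), safe for -Inf arguments.
log_sum_exp2 <- function(a, b) {
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  out <- hi + log1p(exp(lo - hi))
  out[hi == -Inf] <- -Inf
  out
}

check_counts <- function(x, name) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x < 0) ||
      any(x != floor(x))) {
    stop("`", name, "` must contain non-negative integers.", call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be finite and > 0.", call. = FALSE)
  }
  invisible(x)
}
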