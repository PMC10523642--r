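#' Summary characteristics of a count outcome
#'
#' Computes the eight outcome characteristics used as meta-regression
#' predictors of model preference: overall mean and variance,
#' percentage of zero counts (0-100 scale), mean/variance/skewness of
#' the non-zero part, and the marginal NB maximum-likelihood estimates
#' of the success probability `p` and dispersion `r`.  Also sets
#' `is_zero_inflated`, defined operationally as more than 60% zeros
#' together with overdispersion (variance exceeding the mean).
#'
#' Variances use the n-1 denominator.  Skewness is the adjusted
#' Fisher-Pearson standardised third moment,
#' \eqn{g_1 \sqrt{n(n-1)}/(n-2)} (the common default in mainstream
#' statistics software); set `adjust_skewness = FALSE` for the plain
#' moment estimator.  With fewer than 3 distinct non-zero values the
#' skewness is undefined and returned as `NA` with
#' `skewness_defined = FALSE`.
#'
#' @param counts Vector of non-negative integer counts, length >= 3,
#'   not all zero.
#' @param adjust_skewness Use the adjusted (sample-size corrected)
#'   skewness estimator. Default `TRUE`.
#' @return A one-row tibble: `overall_mean`, `overall_variance`,
#'   `pct_zero`, `nonzero_mean`, `nonzero_variance`,
#'   `nonzero_skewness`, `mle_p`, `mle_r`, `is_zero_inflated`,
#'   `skewness_defined`, `poisson_limit` (dispersion capped because
#'   the sample was not overdispersed).
#' @examples
#' compute_characteristics(c(0, 0, 0, 1, 2, 3))
#' @export
compute_characteristics <- function(counts, adjust_skewness = TRUE) {
  check_counts(counts, "counts")
  if (length(counts) < 3) {
    stop("Need at least 3 observations.", call. = FALSE)
  }
  if (all(counts == 0)) {
    stop("All counts are zero: characteristics are undefined for an ",
         "all-zero outcome.", call. = FALSE)
  }
  nz <- counts[counts > 0]
  overall_mean <- mean(counts)
  overall_variance <- stats::var(counts)
  pct_zero <- 100 * mean(counts == 0)

  skew_defined <- length(nz) >= 3 && stats::var(nz) > 0
  skew <- if (skew_defined) sample_skewness(nz, adjust_skewness) else NA_real_

  mle <- marginal_nb_mle(counts)

  tibble::tibble(
    overall_mean = overall_mean,
    overall_variance = overall_variance,
    pct_zero = pct_zero,
    nonzero_mean = mean(nz),
    nonzero_variance = if (length(nz) >= 2) stats::var(nz) else NA_real_,
    nonzero_skewness = skew,
    mle_p = mle$mle_p,
    mle_r = mle$mle_r,
    is_zero_inflated = pct_zero > 60 && overall_variance > overall_mean,
    skewness_defined = skew_defined,
    poisson_limit = mle$poisson_limit
  )
}

sample_skewness <- function(x, adjust = TRUE) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2) # biased (1/n) variance, per the moment estimator
  g1 <- mean((x - m)^3) / s2^1.5
  if (adjust && n > 2) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' Marginal negative binomial maximum-likelihood estimates
#'
#' Fits a covariate-free NB distribution by maximum likelihood.  The
#' score equation fixes the mean parameter at the sample mean; the
#' dispersion maximises the profile log-likelihood in one dimension
#' (optimised on the log scale).  The reported success probability is
#' \eqn{\hat p = \hat r / (\hat r + \hat m)}.  When the sample is not
#' overdispersed the dispersion MLE diverges; it is then capped at
#' `1e6` and `poisson_limit` is set.
#'
#' @param counts Vector of non-negative integer counts, not all zero.
#' @return A list: `mle_m`, `mle_r`, `mle_p`, `log_likelihood`,
#'   `poisson_limit`.
#' @examples
#' set.seed(1)
#' marginal_nb_mle(rnbinom(500, mu = 2, size = 1))
#' @export
marginal_nb_mle <- function(counts) {
  check_counts(counts, "counts")
  if (all(counts == 0)) {
    stop("All counts are zero: NB mean is not identified.", call. = FALSE)
  }
  m_hat <- mean(counts)
  prof <- function(log_r) {
    r <- exp(log_r)
    sum(lgamma(r + counts) - lgamma(r) - lgamma(counts + 1) +
          r * (log(r) - log(r + m_hat)) +
          counts * (log(m_hat) - log(r + m_hat)))
  }
  opt <- stats::optimize(prof, lower = log(1e-4), upper = log(1e6),
                         maximum = TRUE, tol = 1e-10)
  r_hat <- exp(opt$maximum)
  poisson_limit <- r_hat > 1e5 || stats::var(counts) <= m_hat
  if (poisson_limit) r_hat <- min(max(r_hat, 1e5), 1e6)
  list(mle_m = m_hat,
       mle_r = r_hat,
       mle_p = r_hat / (r_hat + m_hat),
       log_likelihood = prof(log(r_hat)),
       poisson_limit = poisson_limit)
}
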