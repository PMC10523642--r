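#' Profile-likelihood confidence interval for a count-part coefficient
#'
#' Inverts the likelihood-ratio statistic for one count-part
#' coefficient: the endpoints are the two values of \eqn{\beta_j} at
#' which \eqn{2\{\ell_{\max} - \ell_p(\beta_j)\}} equals the
#' \eqn{\chi^2_1} quantile of the requested level, where
#' \eqn{\ell_p} maximises over every other parameter (remaining count
#' coefficients, logit coefficients and the log-dispersion).  Roots are
#' found by bracketed search starting from the Wald interval and
#' expanding geometrically; the inner maximisations are warm-started
#' from the neighbouring solution.  When profiling cannot be carried
#' out (no usable curvature, inner failures) a normal-approximation
#' interval is returned with `method = "wald_fallback"`.  A profile
#' that never crosses the threshold on one side (monotone likelihood)
#' yields an infinite endpoint and `monotone = TRUE`.
#'
#' @param fit A converged `"count_model_fit"`.
#' @param data The `"regression_data"` the fit used (defaults to the
#'   data stored on the fit).
#' @param coefficient_index Index of the count-part coefficient to
#'   profile (1 = intercept).
#' @param level Confidence level in (0, 1). Default 0.95.
#' @return A list of class `"profile_interval"`: `lower`, `upper`,
#'   `level`, `method` (`"profile"` or `"wald_fallback"`),
#'   `monotone`.
#' @export
profile_ci <- function(fit, data = fit$data, coefficient_index,
                       level = 0.95) {
  stopifnot(inherits(fit, "count_model_fit"),
            inherits(data, "regression_data"),
            level > 0, level < 1)
  q <- ncol(data$count_covariates)
  j <- as.integer(coefficient_index)
  stopifnot(j >= 1, j <= q)

  theta_hat <- fit$theta
  ll_max <- fit$log_likelihood
  crit <- stats::qchisq(level, df = 1)
  est <- theta_hat[j]

  se <- NA_real_
  if (!is.null(fit$vcov)) se <- sqrt(max(fit$vcov[j, j], 0))
  if (!is.finite(se) || se <= 0) se <- max(abs(est), 0.5)
  z <- stats::qnorm(1 - (1 - level) / 2)
  wald <- c(est - z * se, est + z * se)

  nll <- make_nll(data$outcome, data$count_covariates,
                  data$logit_covariates, data$offset_log, fit$family)
  grad <- make_grad(data$outcome, data$count_covariates,
                    data$logit_covariates, data$offset_log, fit$family)

  # profiled LR statistic minus the chi-square threshold, warm-started
  warm <- new.env(parent = emptyenv())
  warm$theta <- theta_hat
  lr_gap <- function(bj) {
    if (length(theta_hat) == 1L) {
      # no nuisance parameters: the profile is the likelihood itself
      return(2 * (ll_max + nll(bj)) - crit)
    }
    fixed <- function(th_rest) {
      th <- append_at(th_rest, bj, j)
      nll(th)
    }
    fixed_gr <- function(th_rest) {
      th <- append_at(th_rest, bj, j)
      grad(th)[-j]
    }
    start <- warm$theta[-j]
    res <- tryCatch(
      stats::optim(start, fixed, fixed_gr, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) return(NA_real_)
    # Newton polish removes the warm-start path dependence: the
    # profiled value must not depend on where the inner search began
    pol <- newton_polish(res$par, fixed, fixed_gr, max_steps = 5)
    warm$theta <- append_at(pol$theta, bj, j)
    2 * (ll_max + pol$value) - crit
  }

  find_root <- function(direction) {
    warm$theta <- theta_hat
    step <- z * se
    b_in <- est
    b_out <- if (direction < 0) wald[1] else wald[2]
    g_in <- -crit # at the MLE the LR statistic is zero
    g_out <- lr_gap(b_out)
    if (is.na(g_out)) return(list(root = NA_real_, monotone = FALSE))
    tries <- 0
    while (g_out < 0 && tries < 30) {
      step <- step * 1.6
      b_in <- b_out
      g_in <- g_out
      b_out <- b_out + direction * step
      g_out <- lr_gap(b_out)
      if (is.na(g_out)) return(list(root = NA_real_, monotone = FALSE))
      tries <- tries + 1
    }
    if (g_out < 0) {
      return(list(root = direction * Inf, monotone = TRUE))
    }
    lower <- min(b_in, b_out); upper <- max(b_in, b_out)
    f_lower <- if (lower == b_in) g_in else g_out
    f_upper <- if (lower == b_in) g_out else g_in
    root <- tryCatch(
      stats::uniroot(lr_gap, lower = lower, upper = upper,
                     f.lower = f_lower, f.upper = f_upper,
                     tol = 1e-6)$root,
      error = function(e) NA_real_
    )
    list(root = root, monotone = FALSE)
  }

  lo <- find_root(-1)
  hi <- find_root(+1)
  if (is.na(lo$root) || is.na(hi$root)) {
    return(structure(list(lower = wald[1], upper = wald[2], level = level,
                          method = "wald_fallback", monotone = FALSE),
                     class = "profile_interval"))
  }
  structure(list(lower = lo$root, upper = hi$root, level = level,
                 method = "profile",
                 monotone = lo$monotone || hi$monotone),
            class = "profile_interval")
}

append_at <- function(rest, value, j) {
  n <- length(rest) + 1L
  th <- numeric(n)
  th[j] <- value
  th[-j] <- rest
  th
}

#' @export
print.profile_interval <- function(x, ...) {
  cat(sprintf("<profile_interval> %g%% [%.*g, %.*g] (%s)\n",
              100 * x$level, 6, x$lower, 6, x$upper, x$method))
  invisible(x)
}
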