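# Shared fixture builders. Everything is generated in code under a
# caller-supplied seed; no data files.

# Small trial-shaped dataset simulated from known NB/ZINB coefficients.
make_trial_df <- function(n = 300, family = c("nb", "zinb"),
                          beta = c(0.5, -0.49, -0.74, -0.74, -1.86),
                          gamma = c(-2, -1), r = 0.4, seed = 1) {
  family <- match.arg(family)
  set.seed(seed)
  df <- tibble::tibble(
    treatment = stats::rbinom(n, 1, 0.5),
    age_ge2 = stats::rbinom(n, 1, 0.6),
    risk2 = stats::rbinom(n, 1, 0.3),
    risk3 = stats::rbinom(n, 1, 0.2)
  )
  eta <- beta[1] + beta[2] * df$treatment + beta[3] * df$age_ge2 +
    beta[4] * df$risk2 + beta[5] * df$risk3
  y <- stats::rnbinom(n, size = r, mu = exp(eta))
  if (family == "zinb") {
    p <- stats::plogis(gamma[1] + gamma[2] * df$treatment)
    y[stats::runif(n) < p] <- 0L
  }
  df$y <- as.integer(y)
  df$offset_log <- 0
  df
}

# Calibrated generative models, computed once per test run.
calibrated_model <- local({
  cache <- list()
  function(family) {
    if (is.null(cache[[family]])) {
      cache[[family]] <<- calibrate_intercepts(
        generative_model("serious_illness", family)
      )
    }
    cache[[family]]
  }
})

# Hand-built replicate records for the summary-operation tests.
make_records <- function(est_nb, est_zinb = est_nb, aic_nb, aic_zinb,
                         lo = est_nb - 1, hi = est_nb + 1,
                         excluded_nb = FALSE, excluded_zinb = FALSE) {
  k <- length(est_nb)
  tibble::tibble(
    replicate = rep(seq_len(k), 2),
    rep_seed = rep(seq_len(k), 2),
    family = rep(c("nb", "zinb"), each = k),
    estimate = c(est_nb, est_zinb),
    ci_lower = c(lo, rep(NA_real_, k)),
    ci_upper = c(hi, rep(NA_real_, k)),
    ci_method = rep(c("profile", NA), each = k),
    log_likelihood = 0, aic = c(aic_nb, aic_zinb),
    converged = TRUE, boundary_flag = FALSE,
    excluded = c(rep_len(excluded_nb, k), rep_len(excluded_zinb, k)),
    exclusion_reason = ""
  )
}

# Records with a planted association between the characteristics and
# the AIC preference, for exercising the meta-regression pipeline.
make_pref_records <- function(k = 400, seed = 61, signal = TRUE) {
  set.seed(seed)
  chars <- tibble::tibble(
    overall_mean = runif(k, 0.3, 1.5),
    overall_variance = runif(k, 0.5, 6),
    pct_zero = runif(k, 50, 85),
    nonzero_mean = runif(k, 1.3, 3.5),
    nonzero_variance = runif(k, 0.5, 10),
    nonzero_skewness = runif(k, 1, 5),
    mle_p = runif(k, 0.1, 0.6),
    mle_r = runif(k, 0.05, 0.7)
  )
  lp <- if (signal) -1 + 1.2 * scale(chars$nonzero_mean)[, 1] else
    rep(-0.5, k)
  pref <- rbinom(k, 1, plogis(lp))
  aic_nb <- 100 + rnorm(k)
  base <- tibble::tibble(
    replicate = seq_len(k), rep_seed = seq_len(k),
    estimate = rnorm(k, -0.5, 0.2),
    ci_lower = NA_real_, ci_upper = NA_real_, ci_method = NA_character_,
    log_likelihood = 0,
    converged = TRUE, boundary_flag = FALSE,
    excluded = FALSE, exclusion_reason = ""
  )
  dplyr::bind_rows(
    dplyr::mutate(base, family = "nb", aic = aic_nb, chars),
    dplyr::mutate(base, family = "zinb",
                  aic = aic_nb + ifelse(pref == 1, -1, 1), chars)
  )
}
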