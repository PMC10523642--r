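test_that("intercept-only NB fit fixes the mean at the sample mean", {
  set.seed(3)
  y <- rnbinom(400, size = 0.5, mu = 1.4)
  rd <- regression_data(y, matrix(1, length(y), 1,
                                  dimnames = list(NULL, "(Intercept)")))
  fit <- fit_count_model(rd, "nb")
  expect_true(fit$converged)
  expect_equal(exp(fit$count_coefficients[[1]]), mean(y), tolerance = 1e-6)
})

test_that("NB regression recovers known coefficients at n = 5000", {
  beta <- c(0.5, -0.49, -0.74, -0.74, -1.86)
  df <- make_trial_df(n = 5000, family = "nb", beta = beta, r = 0.4,
                      seed = 11)
  fit <- fit_count_model(df, "nb")
  expect_true(fit$converged)
  td <- tidy(fit)
  est <- td$estimate[td$part == "count"]
  se <- td$std_error[td$part == "count"]
  expect_true(all(abs(est - beta) < 3 * se))
  expect_lt(abs(fit$dispersion_r - 0.4), 3 * td$std_error[td$part == "dispersion"])
})

test_that("fitted likelihood equals the sum of the pmf at the optimum", {
  df <- make_trial_df(n = 300, family = "zinb", seed = 5)
  fit <- fit_count_model(df, "zinb")
  eta <- as.matrix(cbind(1, df[c("treatment", "age_ge2", "risk2", "risk3")])) %*%
    fit$count_coefficients
  p <- plogis(fit$logit_coefficients[1] +
                fit$logit_coefficients[2] * df$treatment)
  ll <- sum(zinb_log_pmf(df$y, p, exp(drop(eta)), fit$dispersion_r))
  expect_equal(ll, fit$log_likelihood, tolerance = 1e-8)
})

test_that("ZINB nests NB: likelihood never lower, AIC gap bounded", {
  for (seed in 1:8) {
    df <- make_trial_df(n = 150, family = sample(c("nb", "zinb"), 1),
                        seed = seed)
    fnb <- fit_count_model(df, "nb")
    fzi <- fit_count_model(df, "zinb")
    expect_gte(fzi$log_likelihood, fnb$log_likelihood - 1e-4)
    expect_lte(fzi$aic - fnb$aic, 4 + 1e-4)
  }
})

test_that("ZINB likelihood with the logit part pushed to -30 matches NB", {
  df <- make_trial_df(n = 300, family = "nb", seed = 9)
  fnb <- fit_count_model(df, "nb")
  eta <- as.matrix(cbind(1, df[c("treatment", "age_ge2", "risk2", "risk3")])) %*%
    fnb$count_coefficients
  ll_zinb <- sum(zinb_log_pmf(df$y, plogis(-30), exp(drop(eta)),
                              fnb$dispersion_r))
  expect_equal(ll_zinb, fnb$log_likelihood, tolerance = 1e-3)
})

test_that("AIC counts every freely estimated parameter", {
  df <- make_trial_df(n = 200, family = "zinb", seed = 2)
  fnb <- fit_count_model(df, "nb")
  fzi <- fit_count_model(df, "zinb")
  fpo <- fit_count_model(df, "poisson")
  fzp <- fit_count_model(df, "zip")
  expect_identical(fnb$n_params, 6L) # 5 count coefficients + dispersion
  expect_identical(fzi$n_params, 8L) # + logit intercept and treatment
  expect_identical(fpo$n_params, 5L)
  expect_identical(fzp$n_params, 7L)
  expect_equal(model_aic(fnb), 12 - 2 * fnb$log_likelihood)
  expect_equal(model_aic(fzi), 16 - 2 * fzi$log_likelihood)
  bad <- fnb
  bad$log_likelihood <- NaN
  expect_error(model_aic(bad), "not finite")
})

test_that("fit agrees with independent NB and ZINB implementations", {
  skip_if_not_installed("MASS")
  df <- make_trial_df(n = 500, family = "nb", seed = 13)
  fit <- fit_count_model(df, "nb")
  oracle <- MASS::glm.nb(y ~ treatment + age_ge2 + risk2 + risk3, data = df)
  expect_equal(unname(fit$count_coefficients), unname(coef(oracle)),
               tolerance = 1e-4)
  expect_equal(unname(fit$dispersion_r), unname(oracle$theta),
               tolerance = 1e-4)

  skip_if_not_installed("glmmTMB")
  dfz <- make_trial_df(n = 500, family = "zinb", seed = 14)
  fz <- fit_count_model(dfz, "zinb")
  tmb <- glmmTMB::glmmTMB(y ~ treatment + age_ge2 + risk2 + risk3,
                          ziformula = ~treatment, data = dfz,
                          family = glmmTMB::nbinom2())
  expect_equal(fz$log_likelihood, as.numeric(logLik(tmb)), tolerance = 1e-5)
  expect_equal(unname(fz$count_coefficients),
               unname(glmmTMB::fixef(tmb)$cond), tolerance = 1e-3)
})

test_that("variance estimates are non-negative for clean fits", {
  for (seed in 1:5) {
    df <- make_trial_df(n = 250, family = "zinb", seed = 20 + seed)
    fit <- fit_count_model(df, "zinb")
    if (fit$converged && !fit$boundary_flag) {
      expect_true(all(diag(fit$vcov) >= 0))
    }
  }
})

test_that("degenerate inputs raise informative errors", {
  df <- make_trial_df(n = 100, seed = 1)
  df$dup <- df$treatment
  expect_error(fit_count_model(df, "nb"), "Singular")
  df0 <- tibble::tibble(y = rep(0L, 100), treatment = rep(0:1, 50),
                        offset_log = 0)
  expect_error(fit_count_model(df0, "nb"), "all zero")
})
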