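test_that("preference dataset codes the outcome and standardises", {
  recs <- make_pref_records()
  ds <- build_preference_dataset(recs)
  wide <- tidyr::pivot_wider(
    dplyr::select(recs, "replicate", "family", "aic"),
    names_from = "family", values_from = "aic"
  )
  expect_identical(ds$zinb_preferred,
                   as.integer(wide$zinb < wide$nb))
  for (nm in zinbsim:::characteristic_names) {
    expect_lt(abs(mean(ds[[nm]])), 1e-9)
    expect_equal(sd(ds[[nm]]), 1, tolerance = 1e-9)
  }
  # excluded replicates never reach the dataset
  recs2 <- recs
  recs2$excluded[recs2$replicate == 1] <- TRUE
  kept <- apply_exclusions(recs2)$kept
  ds2 <- build_preference_dataset(kept)
  expect_false(1 %in% ds2$replicate)
})

test_that("undefined skewness rows are dropped and counted", {
  recs <- make_pref_records(k = 120)
  recs$nonzero_skewness[recs$replicate %in% 1:5] <- NA
  ds <- build_preference_dataset(recs)
  expect_identical(attr(ds, "n_dropped_skewness"), 5L)
  expect_identical(nrow(ds), 115L)
})

test_that("heavy shrinkage pulls every adjusted OR to 1", {
  ds <- build_preference_dataset(make_pref_records())
  fit <- fit_ridge_logistic(ds, lambda_grid = c(1e4, 2e4), cv_folds = 5)
  expect_true(all(abs(fit$adjusted_or - 1) < 1e-3))
})

test_that("vanishing penalty recovers the unpenalised logistic fit", {
  ds <- build_preference_dataset(make_pref_records(k = 600))
  fit <- fit_ridge_logistic(ds, lambda_grid = c(1e-7, 5e-8), cv_folds = 5)
  glm_fit <- glm(
    reformulate(zinbsim:::characteristic_names, "zinb_preferred"),
    family = binomial(), data = ds
  )
  expect_equal(unname(fit$coefficients),
               unname(coef(glm_fit)[-1]), tolerance = 1e-4)
})

test_that("ridge coefficient norms shrink monotonically in lambda", {
  ds <- build_preference_dataset(make_pref_records())
  grid <- exp(seq(log(10), log(1e-4), length.out = 30))
  norms <- vapply(grid, function(lam) {
    f <- fit_ridge_logistic(ds, lambda_grid = c(lam, lam * 0.999),
                            cv_folds = 3)
    sqrt(sum(f$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) >= -1e-8)) # grid is decreasing in lambda
})

test_that("planted predictor dominates the adjusted odds ratios", {
  ds <- build_preference_dataset(make_pref_records(signal = TRUE))
  fit <- fit_ridge_logistic(ds)
  ors <- fit$adjusted_or
  expect_identical(names(which.max(ors)), "nonzero_mean")
  expect_gt(max(ors), 1)
})

test_that("unadjusted ORs respect the rescaling identity and the null", {
  ds <- build_preference_dataset(make_pref_records())
  u <- unadjusted_ors(ds)
  scaling <- attr(ds, "scaling")
  for (i in seq_len(nrow(u))) {
    sd_i <- scaling$sd[scaling$predictor == u$predictor[i]]
    expect_equal(u$or_raw[i], u$or_std[i]^(1 / sd_i), tolerance = 1e-6)
  }
  # independent predictor: OR near 1 at large n
  ds_null <- build_preference_dataset(make_pref_records(k = 5000,
                                                        signal = FALSE))
  u0 <- unadjusted_ors(ds_null)
  expect_true(all(u0$or_std > 0.9 & u0$or_std < 1.1))
  expect_false(any(u0$separation))
})

test_that("single-class outcomes and separation are handled", {
  recs <- make_pref_records(k = 100)
  ds <- build_preference_dataset(recs)
  ds_one <- ds
  ds_one$zinb_preferred <- 0L
  expect_error(fit_ridge_logistic(ds_one), "single class")
  # perfectly separating predictor -> infinite-OR sentinel, no crash
  ds_sep <- ds
  ds_sep$nonzero_mean <- scale(ds$zinb_preferred +
    seq(0, 1e-3, length.out = nrow(ds)))[, 1]
  u <- unadjusted_ors(ds_sep)
  expect_true(u$separation[u$predictor == "nonzero_mean"])
  expect_identical(u$or_std[u$predictor == "nonzero_mean"], Inf)
})
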