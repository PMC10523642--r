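test_that("predictor draws are reproducible and well formed", {
  set.seed(31)
  a <- draw_predictors(422)
  set.seed(31)
  b <- draw_predictors(422)
  expect_identical(a, b)
  # one-hot risk coding
  expect_true(all(a$risk2 + a$risk3 <= 1))
  expect_true(all(a$age >= 0 & a$age <= 18))
  expect_identical(a$age_ge2, as.integer(a$age >= 2))
  expect_error(draw_predictors(50), "60")
})

test_that("treated fraction concentrates around the drawn probability", {
  set.seed(32)
  for (i in 1:10) {
    pr <- draw_predictors(422)
    p <- attr(pr, "hyperparams")$treatment_prob
    expect_true(p >= 0.45 && p <= 0.55)
    bound <- 5 * sqrt(p * (1 - p) / 422)
    expect_lt(abs(mean(pr$treatment) - p), bound)
  }
})

test_that("NB zero fraction matches the closed-form zero mass", {
  # constant mean 0.5 and dispersion 0.36: zero mass (r/(r+m))^r
  mod <- generative_model("serious_illness", "nb",
                          beta0 = log(0.5), dispersion_r = 0.36)
  mod$count_coefficients[2:5] <- 0
  set.seed(33)
  pr <- draw_predictors(1000)
  y <- unlist(replicate(100, simulate_outcome(mod, pr), simplify = FALSE))
  p0 <- (0.36 / 0.86)^0.36
  expect_equal(p0, 0.731, tolerance = 1e-3)
  se <- sqrt(p0 * (1 - p0) / length(y))
  expect_lt(abs(mean(y == 0) - p0), 3 * se)
})

test_that("ZINB draws match the mixture moments and the p -> 0 limit", {
  mod <- generative_model("serious_illness", "zinb",
                          beta0 = log(1), dispersion_r = 0.5,
                          gamma0 = qlogis(0.3))
  mod$count_coefficients[2:5] <- 0
  mod$logit_coefficients[2] <- 0
  set.seed(34)
  pr <- draw_predictors(1000)
  y <- unlist(replicate(1000, simulate_outcome(mod, pr), simplify = FALSE))
  mom <- zinb_moments(0.3, 1, 0.5)
  expect_lt(abs(mean(y) - mom$mean), 3 * sqrt(mom$variance / length(y)))

  # gamma -> -30 collapses the mixture onto the NB component
  mod_nb <- mod
  mod_nb$logit_coefficients[1] <- -30
  set.seed(35)
  y_zi <- unlist(replicate(100, simulate_outcome(mod_nb, pr),
                           simplify = FALSE))
  set.seed(36)
  nb_only <- generative_model("serious_illness", "nb",
                              beta0 = log(1), dispersion_r = 0.5)
  nb_only$count_coefficients[2:5] <- 0
  y_nb <- unlist(replicate(100, simulate_outcome(nb_only, pr),
                           simplify = FALSE))
  cap <- 8
  tab <- rbind(table(factor(pmin(y_zi, cap), levels = 0:cap)),
               table(factor(pmin(y_nb, cap), levels = 0:cap)))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("simulate_trial is a pure function of model and seed", {
  mod <- calibrated_model("nb")
  a <- simulate_trial(mod, n = 100, seed = 99)
  b <- simulate_trial(mod, n = 100, seed = 99)
  expect_identical(a$y, b$y)
  expect_identical(a$treatment, b$treatment)
  expect_identical(nrow(a), 100L)
})

test_that("linear-predictor overflow is reported, not silently wrapped", {
  mod <- generative_model("serious_illness", "nb",
                          beta0 = 100, dispersion_r = 1)
  set.seed(37)
  pr <- draw_predictors(60)
  expect_error(simulate_outcome(mod, pr), "overflow")
})

test_that("calibration solves the closed-form identity case", {
  # all slopes zero, offset zero, target mean 1 -> intercept exactly 0
  mod <- generative_model("serious_illness", "nb")
  mod$count_coefficients[2:5] <- 0
  cal <- calibrate_intercepts(mod, targets = list(mean = 1, pct_zero = 55),
                              n_batch = 20, seed = 5)
  expect_equal(cal$count_coefficients[[1]], 0, tolerance = 1e-9)
  # with m = 1 constant, zero mass (r/(r+1))^r = 0.55 pins r
  r <- cal$dispersion_r
  expect_equal((r / (r + 1))^r, 0.55, tolerance = 1e-5)
})

test_that("zero fraction is monotone in the intercepts", {
  mod <- calibrated_model("zinb")
  set.seed(38)
  pr <- draw_predictors(500)
  zero_prob <- function(beta0, gamma0) {
    m <- mod
    m$count_coefficients[1] <- beta0
    m$logit_coefficients[1] <- gamma0
    eta <- zinbsim:::linear_predictor(m, pr)
    p <- plogis(gamma0 + m$logit_coefficients[2] * pr$treatment)
    mean(exp(zinb_log_pmf(rep(0L, nrow(pr)), p, exp(eta), m$dispersion_r)))
  }
  b0 <- mod$count_coefficients[[1]]
  g0 <- mod$logit_coefficients[[1]]
  along_b <- vapply(b0 + seq(-1, 1, 0.25), zero_prob, numeric(1),
                    gamma0 = g0)
  expect_true(all(diff(along_b) < 0)) # more mean, fewer zeros
  along_g <- vapply(g0 + seq(-1, 1, 0.25), function(g)
    zero_prob(b0, g), numeric(1))
  expect_true(all(diff(along_g) > 0)) # more structural zeros
})

test_that("calibrated primary model reproduces the target zero percentage", {
  mod <- calibrated_model("nb")
  set.seed(39)
  pz <- vapply(1:200, function(i) {
    pr <- draw_predictors(422)
    mean(simulate_outcome(mod, pr) == 0) * 100
  }, numeric(1))
  expect_lt(abs(median(pz) - 69.9), 2)
  means <- vapply(1:200, function(i) {
    pr <- draw_predictors(422)
    mean(simulate_outcome(mod, pr))
  }, numeric(1))
  expect_lt(abs(median(means) - 0.68), 0.07)
})

test_that("unattainable calibration targets fail with the achieved range", {
  mod <- generative_model("serious_illness", "nb")
  expect_error(
    calibrate_intercepts(mod, targets = list(mean = 0.1, pct_zero = 5),
                         n_batch = 10, seed = 2),
    "unattainable"
  )
})

test_that("synthetic outcomes stay overdispersed under the NB truth", {
  mod <- calibrated_model("nb")
  set.seed(40)
  for (i in 1:10) {
    y <- simulate_trial(mod, n = 422, seed = 400 + i)$y
    expect_gt(var(y), mean(y))
  }
})
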