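#' Simulate a count outcome from a generative model
#'
#' For each subject the count mean is \eqn{m_i = \exp(x_i'\beta + o)}.
#' Under an NB model the outcome is an NB(\eqn{m_i}, r) draw; under a
#' ZINB model a structural zero is drawn first with probability
#' \eqn{p_i = \mathrm{logistic}(\gamma_0 + \gamma_1 \mathrm{trt}_i)},
#' otherwise the NB draw is used.
#'
#' @param model A calibrated `"generative_model"`.
#' @param predictors Predictor tibble from [draw_predictors()] (columns
#'   `treatment`, `age_ge2`, `risk2`, `risk3`).
#' @return Integer vector of counts, length `nrow(predictors)`.
#' @export
simulate_outcome <- function(model, predictors) {
  stopifnot(inherits(model, "generative_model"))
  if (!all(is.finite(model$count_coefficients)) ||
      !is.finite(model$dispersion_r)) {
    stop("Generative model is not calibrated: intercept or dispersion ",
         "is missing. Run calibrate_intercepts() first.", call. = FALSE)
  }
  eta <- linear_predictor(model, predictors)
  if (any(eta > 50)) {
    stop("Linear predictor overflow (max eta = ",
         format(max(eta), digits = 4), ").", call. = FALSE)
  }
  m <- exp(eta)
  n <- length(m)
  y <- stats::rnbinom(n, size = model$dispersion_r, mu = m)
  if (model$family == "zinb") {
    p <- stats::plogis(model$logit_coefficients[1] +
                         model$logit_coefficients[2] * predictors$treatment)
    y[stats::runif(n) < p] <- 0L
  }
  as.integer(y)
}

linear_predictor <- function(model, predictors) {
  b <- model$count_coefficients
  b[1] + b["treatment"] * predictors$treatment +
    b["age_ge2"] * predictors$age_ge2 +
    b["risk2"] * predictors$risk2 +
    b["risk3"] * predictors$risk3 +
    model$offset_log
}

#' Simulate a complete synthetic trial dataset
#'
#' Draws predictors (with fresh sampling hyperparameters) and an
#' outcome from the generative model, returning the tidy trial table
#' used throughout the package.  With `seed` supplied the dataset is a
#' pure function of `(model, n, seed)`.
#'
#' @inheritParams simulate_outcome
#' @param n Number of subjects (at least 60). Default 422, the size of
#'   the motivating trial.
#' @param seed Optional integer seed for this dataset.
#' @return A tibble with columns `y`, `treatment`, `age_ge2`, `risk2`,
#'   `risk3`, `offset_log`; attributes `"generative_model"`, `"seed"`
#'   and `"hyperparams"`.
#' @examples
#' mod <- generative_model("serious_illness", "nb",
#'                         beta0 = 0.6, dispersion_r = 0.4)
#' simulate_trial(mod, n = 100, seed = 1)
#' @export
simulate_trial <- function(model, n = 422, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  predictors <- draw_predictors(n)
  y <- simulate_outcome(model, predictors)
  out <- tibble::tibble(
    y = y,
    treatment = predictors$treatment,
    age_ge2 = predictors$age_ge2,
    risk2 = predictors$risk2,
    risk3 = predictors$risk3,
    offset_log = rep(model$offset_log, n)
  )
  attr(out, "generative_model") <- model
  attr(out, "seed") <- seed
  attr(out, "hyperparams") <- attr(predictors, "hyperparams")
  out
}
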