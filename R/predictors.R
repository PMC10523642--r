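#' Draw predictor-sampling hyperparameters
#'
#' Each simulation replicate first draws the parameters of its
#' predictor-sampling distributions from uniform ranges reflecting a
#' two-arm pediatric complex-care trial: the randomisation probability
#' from U(0.45, 0.55); the three baseline-risk category probabilities
#' as three U(0.2, 0.45) draws renormalised to sum to one; the mean of
#' the truncated-normal age distribution from U(3, 7) years with a
#' fixed 4-year SD on (0, 18) years.  Every range is overridable.
#'
#' @param treatment_prob_range,risk_prob_range,age_mean_range Numeric
#'   length-2 ranges for the uniform draws.
#' @param age_sd Fixed age standard deviation in years.
#' @param age_bounds Truncation bounds for age, in years.
#' @return A list of class `"predictor_hyperparams"` with elements
#'   `treatment_prob`, `risk_probs` (length 3, sums to 1), `age_mean`,
#'   `age_sd`, `age_bounds`.
#' @export
draw_hyperparams <- function(treatment_prob_range = c(0.45, 0.55),
                             risk_prob_range = c(0.2, 0.45),
                             age_mean_range = c(3, 7),
                             age_sd = 4,
                             age_bounds = c(0, 18)) {
  stopifnot(age_bounds[1] < age_bounds[2], age_sd > 0)
  raw <- stats::runif(3, risk_prob_range[1], risk_prob_range[2])
  structure(
    list(treatment_prob = stats::runif(1, treatment_prob_range[1],
                                       treatment_prob_range[2]),
         risk_probs = raw / sum(raw),
         age_mean = stats::runif(1, age_mean_range[1], age_mean_range[2]),
         age_sd = age_sd,
         age_bounds = age_bounds),
    class = "predictor_hyperparams"
  )
}

#' Draw synthetic trial predictors
#'
#' Generates one replicate's predictor table: treatment arm from a
#' Bernoulli draw, a three-level baseline-risk category from a
#' multinomial draw (level 1 is the reference, dummies `risk2` and
#' `risk3`), and age from a truncated normal, dichotomised at 2 years
#' into the `age_ge2` stratum indicator.  Hyperparameters are drawn
#' fresh via [draw_hyperparams()] unless supplied.
#'
#' Sample sizes below 60 are rejected: with roughly 70% zero counts, a
#' smaller trial leaves too few non-zero observations for stable
#' count-regression fits, so such scenarios are excluded by design.
#'
#' @param n Number of subjects, at least 60.
#' @param hyper Optional `"predictor_hyperparams"`; drawn if `NULL`.
#' @param ... Passed to [draw_hyperparams()] when drawing.
#' @return A tibble with columns `treatment`, `age`, `age_ge2`,
#'   `risk2`, `risk3`, and the hyperparameters in attribute
#'   `"hyperparams"`.
#' @examples
#' set.seed(7)
#' draw_predictors(100)
#' @export
draw_predictors <- function(n, hyper = NULL, ...) {
  if (n < 60) {
    stop("Sample sizes below 60 are excluded: too few non-zero counts ",
         "for stable model fitting.", call. = FALSE)
  }
  if (is.null(hyper)) hyper <- draw_hyperparams(...)
  stopifnot(inherits(hyper, "predictor_hyperparams"))

  treatment <- stats::rbinom(n, 1, hyper$treatment_prob)
  risk <- sample.int(3, n, replace = TRUE, prob = hyper$risk_probs)
  age <- rtruncnorm(n, hyper$age_mean, hyper$age_sd, hyper$age_bounds)
  out <- tibble::tibble(
    treatment = treatment,
    age = age,
    age_ge2 = as.integer(age >= 2),
    risk2 = as.integer(risk == 2),
    risk3 = as.integer(risk == 3)
  )
  attr(out, "hyperparams") <- hyper
  out
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, bounds) {
  plo <- stats::pnorm(bounds[1], mean, sd)
  phi <- stats::pnorm(bounds[2], mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
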