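characteristic_names <- c("overall_mean", "overall_variance", "pct_zero",
                          "nonzero_mean", "nonzero_variance",
                          "nonzero_skewness", "mle_p", "mle_r")

#' Build the model-preference dataset for the meta-regression
#'
#' Turns replicate records into the dataset of the preference
#' analysis: a binary outcome `zinb_preferred` (1 when the ZINB fit
#' attained the strictly lower AIC) and the eight outcome
#' characteristics as predictors, standardised to mean zero and unit
#' SD.  The per-predictor centring and scaling are retained so raw-
#' scale odds ratios can be recovered.  Replicates with an undefined
#' non-zero skewness are dropped (counted in the `n_dropped_skewness`
#' attribute); only replicates with both AICs enter.
#'
#' @param records Kept replicate records containing NB and ZINB rows
#'   and characteristic columns.
#' @return A tibble of class `"preference_dataset"`: `zinb_preferred`
#'   plus the eight standardised predictors; attributes `scaling`
#'   (tibble of predictor, mean, sd), `raw` (unstandardised predictor
#'   tibble) and `n_dropped_skewness`.
#' @export
build_preference_dataset <- function(records) {
  wide <- records |>
    dplyr::filter(.data$family %in% c("nb", "zinb")) |>
    dplyr::select("replicate", "family", "aic",
                  dplyr::all_of(characteristic_names)) |>
    tidyr::pivot_wider(names_from = "family", values_from = "aic",
                       names_prefix = "aic_") |>
    dplyr::filter(!is.na(.data$aic_nb) & !is.na(.data$aic_zinb))
  n_skew_na <- sum(is.na(wide$nonzero_skewness))
  wide <- dplyr::filter(wide, !is.na(.data$nonzero_skewness))
  if (nrow(wide) < 50) {
    warning("Only ", nrow(wide),
            " usable replicates for the preference analysis.",
            call. = FALSE)
  }
  raw <- dplyr::select(wide, dplyr::all_of(characteristic_names))
  sds <- purrr::map_dbl(raw, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    stop("Constant predictor column(s): ",
         paste(characteristic_names[sds == 0 | !is.finite(sds)],
               collapse = ", "),
         " cannot be standardised.", call. = FALSE)
  }
  means <- purrr::map_dbl(raw, mean)
  std <- purrr::map2(raw, seq_along(raw),
                     function(col, i) (col - means[i]) / sds[i])
  out <- tibble::tibble(
    replicate = wide$replicate,
    zinb_preferred = as.integer(wide$aic_zinb < wide$aic_nb),
    !!!std
  )
  class(out) <- c("preference_dataset", class(out))
  attr(out, "scaling") <- tibble::tibble(predictor = characteristic_names,
                                         mean = unname(means),
                                         sd = unname(sds))
  attr(out, "raw") <- raw
  attr(out, "n_dropped_skewness") <- n_skew_na
  out
}

#' Ridge logistic regression of model preference on outcome characteristics
#'
#' Fits a penalised logistic regression of the ZINB-preferred
#' indicator on the eight standardised characteristics with an L2
#' penalty on the slopes (intercept unpenalised), the standard remedy
#' for the strong correlation among the characteristics.  The penalty
#' is selected by k-fold cross-validated binomial deviance over a
#' logarithmic grid with a fixed fold seed; the minimum-deviance
#' lambda is used.  Adjusted odds ratios are the exponentiated
#' coefficients at the selected lambda.  Optional nonparametric
#' bootstrap (resampling replicates, refitting at the selected
#' lambda) yields percentile intervals for the ORs.
#'
#' @param dataset A `"preference_dataset"`.
#' @param lambda_grid Penalty grid; default 50 logarithmic points from
#'   1e-4 to 10.
#' @param cv_folds Number of cross-validation folds. Default 10.
#' @param fold_seed Seed fixing the fold assignment (and bootstrap).
#' @param n_boot Bootstrap resamples for OR intervals; 0 disables.
#' @return A list of class `"ridge_preference_fit"`: `lambda`
#'   (selected), `coefficients` (standardised scale, named),
#'   `adjusted_or`, `or_lower`/`or_upper` (when bootstrapped),
#'   `cv_deviance_path` (tibble lambda x mean deviance), `scaling`,
#'   `n`, `n_events`.
#' @export
fit_ridge_logistic <- function(dataset, lambda_grid = NULL, cv_folds = 10,
                               fold_seed = 42, n_boot = 0) {
  stopifnot(inherits(dataset, "preference_dataset"))
  y <- dataset$zinb_preferred
  if (length(unique(y)) < 2) {
    stop("Preference outcome has a single class; ridge logistic ",
         "regression is not identified.", call. = FALSE)
  }
  x <- as.matrix(dataset[characteristic_names])
  if (any(!is.finite(x))) stop("Non-finite predictors.", call. = FALSE)
  if (is.null(lambda_grid)) {
    lambda_grid <- exp(seq(log(10), log(1e-4), length.out = 50))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  foldid <- withr_seed(fold_seed, function() {
    sample(rep_len(seq_len(cv_folds), length(y)))
  })
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lambda_grid, foldid = foldid,
                          standardize = FALSE, type.measure = "deviance",
                          thresh = 1e-12)
  lam <- cv$lambda.min
  co <- stats::coef(cv$glmnet.fit, s = lam)
  beta <- stats::setNames(as.numeric(co)[-1], characteristic_names)

  or_lo <- or_hi <- NULL
  if (n_boot > 0) {
    boot <- withr_seed(fold_seed + 1L, function() {
      replicate(n_boot, {
        idx <- sample.int(length(y), replace = TRUE)
        if (length(unique(y[idx])) < 2) return(rep(NA_real_, ncol(x)))
        fb <- glmnet::glmnet(x[idx, , drop = FALSE], y[idx],
                             family = "binomial", alpha = 0,
                             lambda = lambda_grid, standardize = FALSE,
                             thresh = 1e-10)
        as.numeric(stats::coef(fb, s = lam))[-1]
      })
    })
    qs <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    or_lo <- stats::setNames(exp(qs[1, ]), characteristic_names)
    or_hi <- stats::setNames(exp(qs[2, ]), characteristic_names)
  }

  structure(
    list(lambda = lam,
         coefficients = beta,
         adjusted_or = exp(beta),
         or_lower = or_lo,
         or_upper = or_hi,
         cv_deviance_path = tibble::tibble(lambda = cv$lambda,
                                           cv_deviance = cv$cvm),
         scaling = attr(dataset, "scaling"),
         n = length(y),
         n_events = sum(y)),
    class = "ridge_preference_fit"
  )
}

#' @export
print.ridge_preference_fit <- function(x, ...) {
  cat("<ridge_preference_fit> n =", x$n, "| events =", x$n_events,
      "| lambda =", format(x$lambda, digits = 4), "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a ridge preference fit
#'
#' @param x A `"ridge_preference_fit"`.
#' @param ... Unused.
#' @return A tibble: `predictor`, `coefficient` (standardised scale),
#'   `adjusted_or`, and bootstrap `or_lower`/`or_upper` when present.
#' @method tidy ridge_preference_fit
#' @export
tidy.ridge_preference_fit <- function(x, ...) {
  out <- tibble::tibble(predictor = names(x$coefficients),
                        coefficient = unname(x$coefficients),
                        adjusted_or = unname(x$adjusted_or))
  if (!is.null(x$or_lower)) {
    out$or_lower <- unname(x$or_lower)
    out$or_upper <- unname(x$or_upper)
  }
  out
}

#' @method glance ridge_preference_fit
#' @export
glance.ridge_preference_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n = x$n, n_events = x$n_events,
                 cv_deviance_min = min(x$cv_deviance_path$cv_deviance))
}

#' Univariable odds ratios for model preference
#'
#' One unpenalised single-predictor logistic regression per
#' characteristic, on the standardised scale and back-transformed to
#' the raw scale through the stored scaling (a one-unit raw change is
#' `1/sd` standardised units, so `OR_raw = OR_std^(1/sd)`).  Complete
#' separation yields infinite-OR sentinels and a flag rather than an
#' error.
#'
#' @param dataset A `"preference_dataset"`.
#' @return A tibble: `predictor`, `or_std`, `or_raw`, `separation`.
#' @export
unadjusted_ors <- function(dataset) {
  stopifnot(inherits(dataset, "preference_dataset"))
  y <- dataset$zinb_preferred
  scaling <- attr(dataset, "scaling")
  purrr::map_dfr(characteristic_names, function(nm) {
    xs <- dataset[[nm]]
    fit <- suppressWarnings(
      stats::glm(y ~ xs, family = stats::binomial())
    )
    b <- stats::coef(fit)[["xs"]]
    sep <- !fit$converged || abs(b) > 15
    if (sep) b <- sign(b) * Inf
    sd_nm <- scaling$sd[scaling$predictor == nm]
    tibble::tibble(predictor = nm,
                   or_std = exp(b),
                   or_raw = exp(b / sd_nm),
                   separation = sep)
  })
}
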