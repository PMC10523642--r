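#' Fit the analysis models to one synthetic dataset
#'
#' Fits every requested analysis family to the same dataset, records
#' the count-part treatment coefficient, its profile-likelihood CI,
#' the AIC and the convergence/boundary flags.  Fit failures never
#' propagate: a failed family yields a flagged row with `NA` fields
#' while the other families' rows are unaffected.
#'
#' @param data Trial tibble (columns `y`, `treatment`, `age_ge2`,
#'   `risk2`, `risk3`, `offset_log`) or a `"regression_data"`.
#' @param analysis_families Families to fit. Default NB and ZINB.
#' @param ci_families Families for which to compute the profile CI of
#'   the treatment coefficient (profiling is the expensive step).
#'   Default: all of `analysis_families`.
#' @param level Confidence level for the profile CIs.
#' @return A tibble with one row per analysis family: `family`,
#'   `estimate` (treatment coefficient), `ci_lower`, `ci_upper`,
#'   `ci_method`, `log_likelihood`, `aic`, `converged`,
#'   `boundary_flag`.
#' @export
run_replicate <- function(data, analysis_families = c("nb", "zinb"),
                          ci_families = analysis_families, level = 0.95) {
  rd <- if (inherits(data, "regression_data")) data else
    as_regression_data(data)
  rows <- purrr::map(analysis_families, function(fam) {
    fit <- tryCatch(fit_count_model(rd, fam), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(
        family = fam, estimate = NA_real_, ci_lower = NA_real_,
        ci_upper = NA_real_, ci_method = NA_character_,
        log_likelihood = NA_real_, aic = NA_real_,
        converged = FALSE, boundary_flag = FALSE
      ))
    }
    j <- match("treatment", colnames(rd$count_covariates))
    ci <- list(lower = NA_real_, upper = NA_real_, method = NA_character_)
    if (fam %in% ci_families && fit$converged && !fit$boundary_flag &&
        !is.na(j)) {
      ci_try <- tryCatch(profile_ci(fit, rd, j, level),
                         error = function(e) NULL)
      if (!is.null(ci_try)) ci <- ci_try
    }
    tibble::tibble(
      family = fam,
      estimate = if (is.na(j)) NA_real_ else
        unname(fit$count_coefficients[j]),
      ci_lower = ci$lower, ci_upper = ci$upper,
      ci_method = if (is.null(ci$method)) NA_character_ else ci$method,
      log_likelihood = fit$log_likelihood,
      aic = fit$aic,
      converged = fit$converged,
      boundary_flag = fit$boundary_flag
    )
  })
  dplyr::bind_rows(rows)
}

#' Run a Monte-Carlo replicate study
#'
#' The core replicate loop: for each replicate, draw fresh predictor
#' hyperparameters and predictors, simulate an outcome from the
#' generative model, compute the outcome characteristics, and fit the
#' requested analysis families with profile CIs for the treatment
#' coefficient.  Randomness is keyed per replicate — substream seeds
#' are derived once from `seed` — so any single replicate can be
#' regenerated in isolation and execution order cannot change results.
#'
#' @param model A calibrated `"generative_model"`.
#' @param reps Number of replicates.
#' @param n Subjects per replicate (>= 60). Default 422.
#' @param seed Master seed for the study.
#' @inheritParams run_replicate
#' @param progress Print a dot every 50 replicates.
#' @return A tibble of replicate records, one row per replicate x
#'   analysis family: `replicate`, `rep_seed`, fit columns as in
#'   [run_replicate()], `excluded` and `exclusion_reason`, and the
#'   outcome characteristic columns of [compute_characteristics()].
#' @examples
#' \donttest{
#' mod <- calibrate_intercepts(generative_model("serious_illness", "nb"),
#'                             n_batch = 50, seed = 1)
#' recs <- run_simulation(mod, reps = 5, n = 100, seed = 1,
#'                        ci_families = character())
#' }
#' @export
run_simulation <- function(model, reps, n = 422, seed = 1,
                           analysis_families = c("nb", "zinb"),
                           ci_families = analysis_families,
                           level = 0.95, progress = FALSE) {
  stopifnot(inherits(model, "generative_model"), reps >= 1)
  rep_seeds <- withr_seed(seed, function() {
    sample.int(.Machine$integer.max - 1L, reps)
  })
  out <- purrr::map(seq_len(reps), function(k) {
    if (progress && k %% 50 == 0) cat(".")
    dat <- simulate_trial(model, n = n, seed = rep_seeds[k])
    chars <- tryCatch(compute_characteristics(dat$y),
                      error = function(e) NULL)
    rec <- run_replicate(dat, analysis_families, ci_families, level)
    rec$replicate <- k
    rec$rep_seed <- rep_seeds[k]
    if (!is.null(chars)) {
      rec <- dplyr::bind_cols(rec, chars[rep(1, nrow(rec)), ])
    } else {
      rec$degenerate_outcome <- TRUE
    }
    rec
  })
  records <- dplyr::bind_rows(out)
  if (progress) cat("\n")
  records$excluded <- !records$converged | records$boundary_flag |
    is.na(records$aic)
  records$exclusion_reason <- dplyr::case_when(
    is.na(records$aic) ~ "fit_failed",
    !records$converged ~ "non_convergence",
    records$boundary_flag ~ "boundary",
    TRUE ~ ""
  )
  dplyr::relocate(records, "replicate", "rep_seed", "family")
}

#' Apply per-family exclusions to replicate records
#'
#' Drops rows whose fit did not converge cleanly (non-convergence,
#' boundary solution or outright failure).  Exclusion is per analysis
#' family: a failed ZINB fit does not discard the NB estimate from the
#' same replicate.
#'
#' @param records Replicate records from [run_simulation()].
#' @return A list: `kept` (clean rows) and `report`, a per-family
#'   tibble with `n`, `n_excluded`, `pct_excluded` and a breakdown by
#'   reason.  If every row of a family is excluded a warning is
#'   raised.
#' @export
apply_exclusions <- function(records) {
  stopifnot(all(c("family", "excluded") %in% names(records)))
  report <- records |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_excluded = sum(.data$excluded),
      pct_excluded = 100 * mean(.data$excluded),
      n_non_convergence = sum(.data$exclusion_reason == "non_convergence"),
      n_boundary = sum(.data$exclusion_reason == "boundary"),
      n_fit_failed = sum(.data$exclusion_reason == "fit_failed"),
      .groups = "drop"
    )
  kept <- dplyr::filter(records, !.data$excluded)
  empty <- report$family[report$n_excluded == report$n]
  if (length(empty)) {
    warning("All replicates excluded for: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  list(kept = kept, report = report)
}

#' Bias, MSE and coverage of the treatment coefficient
#'
#' Summarises kept replicate records against the true (data-derived)
#' treatment coefficient.  `absolute_bias` is the mean absolute error
#' \eqn{E|\hat\beta - \beta_{DD}|} and `relative_bias` divides it by
#' \eqn{|\beta_{DD}|}; the signed mean error is reported alongside as
#' `signed_bias`.  `coverage` is the fraction of profile intervals
#' containing the truth, computed over rows with an interval.
#'
#' @param records Kept replicate records (see [apply_exclusions()]).
#' @param beta_dd True treatment coefficient.
#' @param level Nominal CI level (carried through to the output).
#' @return A tibble with one row per analysis family: `family`,
#'   `absolute_bias`, `signed_bias`, `relative_bias`, `mse`,
#'   `coverage`, `n_used`, `n_ci`.
#' @export
summarize_metrics <- function(records, beta_dd, level = 0.95) {
  stopifnot(is.finite(beta_dd))
  est <- dplyr::filter(records, !is.na(.data$estimate))
  if (nrow(est) < 2) {
    stop("Need at least 2 usable replicate estimates.", call. = FALSE)
  }
  est |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      absolute_bias = mean(abs(.data$estimate - beta_dd)),
      signed_bias = mean(.data$estimate - beta_dd),
      relative_bias = mean(abs(.data$estimate - beta_dd)) / abs(beta_dd),
      mse = mean((.data$estimate - beta_dd)^2),
      coverage = {
        has_ci <- !is.na(.data$ci_lower) & !is.na(.data$ci_upper)
        if (any(has_ci)) {
          mean(.data$ci_lower[has_ci] <= beta_dd &
                 beta_dd <= .data$ci_upper[has_ci])
        } else {
          NA_real_
        }
      },
      n_used = dplyr::n(),
      n_ci = sum(!is.na(.data$ci_lower)),
      .groups = "drop"
    ) |>
    dplyr::mutate(level = level)
}

#' Fraction of replicates preferring the NB model by AIC
#'
#' Pairs the NB and ZINB rows of each replicate and reports the
#' fraction in which the NB fit attains the lower AIC.  Exact AIC ties
#' count as NB-preferred (parsimony).  Replicates missing either AIC
#' (excluded or failed fits) are dropped from the denominator and
#' counted in the attached report.
#'
#' @param records Replicate records with both `"nb"` and `"zinb"` rows
#'   (typically the `kept` element of [apply_exclusions()]).
#' @return The NB-preferred fraction, with attributes `n_pairs`
#'   (denominator) and `n_dropped`.
#' @export
preference_fraction <- function(records) {
  wide <- records |>
    dplyr::filter(.data$family %in% c("nb", "zinb")) |>
    dplyr::select("replicate", "family", "aic") |>
    tidyr::pivot_wider(names_from = "family", values_from = "aic",
                       names_prefix = "aic_")
  if (!all(c("aic_nb", "aic_zinb") %in% names(wide))) {
    stop("Records must contain both NB and ZINB fits.", call. = FALSE)
  }
  ok <- !is.na(wide$aic_nb) & !is.na(wide$aic_zinb)
  frac <- mean(wide$aic_nb[ok] <= wide$aic_zinb[ok])
  structure(frac, n_pairs = sum(ok), n_dropped = sum(!ok))
}
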