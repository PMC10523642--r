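#' Build a study configuration
#'
#' Collects every knob of the full simulation study into a validated
#' config object.  `dd_family = "both"` runs the NB-truth and
#' ZINB-truth scenarios; additional sample sizes beyond the base
#' trial size support the sensitivity analysis (only sizes from the
#' studied grid, all at least 60, are accepted).
#'
#' @param outcome Outcome label (see [generative_model()]).
#' @param dd_family Generative family: `"nb"`, `"zinb"` or `"both"`.
#' @param analysis_families Families fitted to each dataset.
#' @param reps Replicates per scenario (>= 2). Default 5000, the full
#'   study size; use a few hundred for desk-scale runs.
#' @param sample_sizes Sample sizes to run; subset of
#'   {60, 80, 100, 200, 422, 600, 800}.
#' @param master_seed Master seed; everything derives from it.
#' @param calibration_targets Optional named list per outcome label
#'   overriding the default `mean`/`pct_zero` targets.
#' @param gamma0 ZINB logit intercept used for ZINB-truth scenarios.
#' @param ci_correct_only Compute profile CIs only for the analysis
#'   family matching the generative family (`TRUE`, default — the
#'   cells coverage is reported for) or for all fitted families.
#' @param lambda_grid,cv_folds,n_boot Ridge-analysis settings (see
#'   [fit_ridge_logistic()]).
#' @param output_dir Directory for CSV outputs and the run log.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(outcome = "serious_illness",
                         dd_family = c("both", "nb", "zinb"),
                         analysis_families = c("nb", "zinb"),
                         reps = 5000,
                         sample_sizes = 422,
                         master_seed = 20260921,
                         calibration_targets = NULL,
                         gamma0 = -2.944,
                         ci_correct_only = TRUE,
                         lambda_grid = NULL,
                         cv_folds = 10,
                         n_boot = 200,
                         output_dir = "zinbsim-output") {
  dd_family <- match.arg(dd_family)
  allowed_n <- c(60, 80, 100, 200, 422, 600, 800)
  if (!all(sample_sizes %in% allowed_n)) {
    bad <- setdiff(sample_sizes, allowed_n)
    stop("Unsupported sample size(s) ", paste(bad, collapse = ", "),
         ": the studied grid is {", paste(allowed_n, collapse = ", "),
         "} and sizes below 60 are excluded by design.", call. = FALSE)
  }
  stopifnot(reps >= 2, master_seed == floor(master_seed))
  if (!outcome %in% c("serious_illness", "days_hospital", "care_days")) {
    stop("Unknown outcome label: ", outcome, call. = FALSE)
  }
  structure(
    list(outcome = outcome, dd_family = dd_family,
         analysis_families = analysis_families, reps = as.integer(reps),
         sample_sizes = as.integer(sample_sizes),
         master_seed = as.integer(master_seed),
         calibration_targets = calibration_targets, gamma0 = gamma0,
         ci_correct_only = ci_correct_only,
         lambda_grid = lambda_grid, cv_folds = cv_folds,
         n_boot = n_boot, output_dir = output_dir),
    class = "study_config"
  )
}

#' Read a study configuration from a YAML file
#'
#' Plain-text key-value configuration; keys mirror the arguments of
#' [study_config()].  Unknown keys are rejected before any
#' computation starts.
#'
#' @param path Path to a YAML file.
#' @return A `"study_config"`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(study_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("Unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(study_config, raw)
}

#' Run the full simulation study
#'
#' Executes the whole pipeline for each generative family and sample
#' size in the config: calibrate the generative model, simulate
#' `reps` trial datasets, fit the analysis models with profile CIs,
#' apply exclusions, summarise bias/MSE/coverage and the AIC
#' preference fractions, and run the ridge preference analysis on the
#' pooled records.  Five CSV outputs plus a plain-text run log are
#' written to `config$output_dir`; a given `(config, master_seed)`
#' reproduces them exactly.
#'
#' Output files: `replicates.csv` (one row per replicate x scenario x
#' analysis family), `metrics.csv` (bias/MSE/coverage by scenario and
#' family), `preference.csv` (NB-preference fractions),
#' `exclusions.csv`, `odds_ratios.csv` (adjusted ridge ORs and
#' univariable ORs) and `run_log.txt`.
#'
#' @param config A `"study_config"`.
#' @return Invisibly, a list with elements `records`, `metrics`,
#'   `preference`, `exclusions`, `odds_ratios`, `models` (the
#'   calibrated generative models) and `files`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  dd_families <- if (config$dd_family == "both") c("nb", "zinb") else
    config$dd_family

  models <- list()
  records <- list()
  for (fam in dd_families) {
    model <- generative_model(config$outcome, fam, gamma0 = config$gamma0)
    model <- calibrate_intercepts(
      model,
      targets = config$calibration_targets[[config$outcome]],
      seed = config$master_seed + 1L
    )
    models[[fam]] <- model
    for (n in config$sample_sizes) {
      scen_seed <- (config$master_seed +
                      1000L * match(fam, c("nb", "zinb")) + n) %%
        .Machine$integer.max
      ci_fams <- if (config$ci_correct_only) {
        intersect(fam, config$analysis_families)
      } else {
        config$analysis_families
      }
      recs <- run_simulation(model, reps = config$reps, n = n,
                             seed = scen_seed,
                             analysis_families = config$analysis_families,
                             ci_families = ci_fams)
      recs$dd_family <- fam
      recs$n <- n
      records[[paste(fam, n, sep = "_")]] <- recs
    }
  }
  records <- dplyr::bind_rows(records)

  scen <- dplyr::group_split(records, .data$dd_family, .data$n)
  metrics <- purrr::map_dfr(scen, function(rr) {
    fam <- rr$dd_family[1]
    kept <- apply_exclusions(rr)$kept
    true_beta <- true_beta_treatment(models[[fam]])
    summarize_metrics(kept, true_beta) |>
      dplyr::mutate(dd_family = fam, n = rr$n[1],
                    beta_dd = true_beta, .before = 1)
  })
  preference <- purrr::map_dfr(scen, function(rr) {
    kept <- apply_exclusions(rr)$kept
    pf <- preference_fraction(kept)
    tibble::tibble(dd_family = rr$dd_family[1], n = rr$n[1],
                   pct_nb_preferred = 100 * as.numeric(pf),
                   n_pairs = attr(pf, "n_pairs"))
  })
  exclusions <- purrr::map_dfr(scen, function(rr) {
    apply_exclusions(rr)$report |>
      dplyr::mutate(dd_family = rr$dd_family[1], n = rr$n[1], .before = 1)
  })

  kept_all <- apply_exclusions(records)$kept
  ridge_note <- ""
  ridge <- NULL
  odds_ratios <- tryCatch({
    pref_data <- build_preference_dataset(kept_all)
    ridge <- fit_ridge_logistic(pref_data, lambda_grid = config$lambda_grid,
                                cv_folds = config$cv_folds,
                                fold_seed = config$master_seed + 7L,
                                n_boot = config$n_boot)
    dplyr::left_join(tidy(ridge), unadjusted_ors(pref_data),
                     by = "predictor")
  }, error = function(e) {
    # small runs can yield a single-class preference outcome; retain the
    # completed stages and log the failure instead of aborting
    ridge_note <<- paste("preference analysis failed:",
                         conditionMessage(e))
    warning(ridge_note, call. = FALSE)
    tibble::tibble(predictor = characteristic_names,
                   coefficient = NA_real_, adjusted_or = NA_real_)
  })

  files <- file.path(config$output_dir,
                     c("replicates.csv", "metrics.csv", "preference.csv",
                       "exclusions.csv", "odds_ratios.csv"))
  readr::write_csv(records, files[1])
  readr::write_csv(metrics, files[2])
  readr::write_csv(preference, files[3])
  readr::write_csv(exclusions, files[4])
  readr::write_csv(odds_ratios, files[5])

  log_path <- file.path(config$output_dir, "run_log.txt")
  writeLines(c(
    paste("zinbsim run", format(t0, "%Y-%m-%d %H:%M:%S")),
    paste("R", getRversion(), "| zinbsim",
          as.character(utils::packageVersion("zinbsim"))),
    paste("outcome:", config$outcome),
    paste("dd_family:", config$dd_family),
    paste("reps:", config$reps),
    paste("sample sizes:", paste(config$sample_sizes, collapse = ", ")),
    paste("master seed:", config$master_seed),
    if (is.null(ridge)) ridge_note else
      paste("ridge lambda selected:", format(ridge$lambda, digits = 6)),
    paste("elapsed (s):",
          round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1))
  ), log_path)

  invisible(list(records = records, metrics = metrics,
                 preference = preference, exclusions = exclusions,
                 odds_ratios = odds_ratios, models = models,
                 files = c(files, log_path)))
}
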