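#' Forest plot of adjusted odds ratios for ZINB preference
#'
#' @param object A `"ridge_preference_fit"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ridge_preference_fit
#' @export
autoplot.ridge_preference_fit <- function(object, ...) {
  td <- tidy(object)
  td$predictor <- stats::reorder(td$predictor, td$adjusted_or)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$adjusted_or,
                                        y = .data$predictor)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Adjusted odds ratio (ZINB preferred)",
                  y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(td$or_lower)) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$or_lower, xmax = .data$or_upper),
      height = 0.2
    )
  }
  p
}

#' Plot treatment-coefficient estimates across replicates
#'
#' Violin plot of the count-part treatment estimates by analysis
#' family, with the true data-derived coefficient as a dashed line.
#'
#' @param records Replicate records from [run_simulation()].
#' @param beta_dd True treatment coefficient (dashed reference line).
#' @return A ggplot.
#' @export
plot_estimates <- function(records, beta_dd = NULL) {
  dat <- dplyr::filter(records, !is.na(.data$estimate))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$family,
                                         y = .data$estimate)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA) +
    ggplot2::labs(x = "Analysis model",
                  y = "Treatment coefficient estimate") +
    ggplot2::theme_minimal()
  if (!is.null(beta_dd)) {
    p <- p + ggplot2::geom_hline(yintercept = beta_dd,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot the cross-validated deviance path of the ridge fit
#'
#' @param fit A `"ridge_preference_fit"`.
#' @return A ggplot of mean CV binomial deviance against log lambda,
#'   with the selected lambda marked.
#' @export
plot_cv_path <- function(fit) {
  stopifnot(inherits(fit, "ridge_preference_fit"))
  ggplot2::ggplot(fit$cv_deviance_path,
                  ggplot2::aes(x = log(.data$lambda),
                               y = .data$cv_deviance)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(fit$lambda),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "log(lambda)", y = "CV binomial deviance") +
    ggplot2::theme_minimal()
}
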