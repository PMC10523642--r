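#' Assemble count-regression data
#'
#' Bundles an outcome, count-part and logit-part design matrices and a
#' log-exposure offset into the container the fitting functions
#' consume.  Most users will instead pass a trial data frame (columns
#' `y`, `treatment`, `age_ge2`, `risk2`, `risk3`, `offset_log`) to
#' [as_regression_data()] or directly to [fit_count_model()].
#'
#' @param outcome Vector of non-negative integer counts.
#' @param count_covariates Numeric matrix (n x q) for the log-link count
#'   mean, including an all-ones intercept column.
#' @param logit_covariates Numeric matrix (n x s) for the logit-link
#'   structural-zero probability, including an intercept column.  Use
#'   `NULL` for families without a zero part.
#' @param offset_log Numeric vector of log exposure (e.g. log follow-up
#'   days), length n.  Defaults to zero exposure adjustment.
#' @return An object of class `"regression_data"`.
#' @export
regression_data <- function(outcome, count_covariates,
                            logit_covariates = NULL, offset_log = NULL) {
  check_counts(outcome, "outcome")
  count_covariates <- as.matrix(count_covariates)
  n <- length(outcome)
  if (nrow(count_covariates) != n) {
    stop("`count_covariates` must have one row per outcome value.",
         call. = FALSE)
  }
  if (is.null(offset_log)) offset_log <- numeric(n)
  if (length(offset_log) == 1) offset_log <- rep(offset_log, n)
  stopifnot(length(offset_log) == n, all(is.finite(offset_log)))
  if (!is.null(logit_covariates)) {
    logit_covariates <- as.matrix(logit_covariates)
    if (nrow(logit_covariates) != n) {
      stop("`logit_covariates` must have one row per outcome value.",
           call. = FALSE)
    }
  }
  check_intercept_col(count_covariates, "count_covariates")
  if (!is.null(logit_covariates)) {
    check_intercept_col(logit_covariates, "logit_covariates")
  }
  structure(
    list(outcome = as.integer(outcome),
         count_covariates = count_covariates,
         logit_covariates = logit_covariates,
         offset_log = as.numeric(offset_log)),
    class = "regression_data"
  )
}

check_intercept_col <- function(mat, name) {
  if (is.null(colnames(mat))) {
    colnames(mat) <- c("(Intercept)", paste0("x", seq_len(ncol(mat) - 1)))
  }
  if (!any(apply(mat, 2, function(col) all(col == 1)))) {
    stop("`", name, "` must include an all-ones intercept column.",
         call. = FALSE)
  }
  invisible(mat)
}

#' Convert a trial data frame to regression data
#'
#' Builds the design matrices used throughout the package from a tidy
#' trial table.  The count part uses the intercept plus all covariate
#' columns; the logit part (for zero-inflated families) uses the
#' intercept plus `zero_covariates` only — by default just `treatment`,
#' mirroring a trial analysis in which only the randomised arm is
#' allowed to shift the structural-zero probability.
#'
#' @param data Data frame with an outcome column, covariate columns and
#'   optionally `offset_log`.
#' @param outcome Name of the outcome column. Default `"y"`.
#' @param covariates Character vector of count-part covariate columns.
#'   Defaults to all columns except the outcome and `offset_log`.
#' @param zero_covariates Character vector of logit-part covariate
#'   columns. Default `"treatment"` when present, else none (intercept
#'   only).
#' @return A `"regression_data"` object.
#' @export
as_regression_data <- function(data, outcome = "y", covariates = NULL,
                               zero_covariates = NULL) {
  data <- as.data.frame(data)
  if (!outcome %in% names(data)) {
    stop("Column `", outcome, "` not found.", call. = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c(outcome, "offset_log"))
  }
  if (is.null(zero_covariates)) {
    zero_covariates <- intersect("treatment", names(data))
  }
  n <- nrow(data)
  xmat <- cbind("(Intercept)" = rep(1, n),
                as.matrix(data[covariates]))
  zmat <- cbind("(Intercept)" = rep(1, n),
                as.matrix(data[zero_covariates]))
  off <- if ("offset_log" %in% names(data)) data$offset_log else numeric(n)
  regression_data(data[[outcome]], xmat, zmat, off)
}

#' @export
print.regression_data <- function(x, ...) {
  cat("<regression_data> n =", length(x$outcome),
      "| count part:", ncol(x$count_covariates), "cols",
      "| logit part:",
      if (is.null(x$logit_covariates)) "none"
      else paste(ncol(x$logit_covariates), "cols"),
      "\n")
  invisible(x)
}
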