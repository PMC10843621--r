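# Prediction metrics and variable-selection summaries.

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, the general form that is
#' valid out-of-sample (and may then be negative). The centering mean is
#' the mean of the evaluation set's true values.
#'
#' @param y True values (length >= 2, not constant).
#' @param yhat Predictions of the same length.
#' @return R-squared (<= 1).
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2) stop("need at least 2 observations")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R-squared is undefined for a constant response")
  1 - sum((y - yhat)^2) / sst
}

#' Mean absolute error
#'
#' @param y True values.
#' @param yhat Predictions of the same length.
#' @return `mean(|y - yhat|)`.
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  mean(abs(y - yhat))
}

#' Root mean squared error
#'
#' @param y True values.
#' @param yhat Predictions of the same length.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  sqrt(mean((y - yhat)^2))
}

#' Count selected variables
#'
#' Number of exactly nonzero coefficients in a fit (the solvers produce
#' exact zeros by thresholding, so no numerical cutoff is applied), plus
#' the selected column names.
#'
#' @param fit A `"coef_fit"`.
#' @param rule Selection rule; only `"exact_zero"` is defined.
#' @return A list with `count` and `names`.
#' @export
count_selected <- function(fit, rule = c("exact_zero")) {
  rule <- match.arg(rule)
  stopifnot(inherits(fit, "coef_fit"))
  sel <- which(fit$beta != 0)
  list(count = length(sel), names = names(fit$beta)[sel])
}

#' Evaluation report for a set of predictions
#'
#' @param y True values.
#' @param yhat Predictions.
#' @param fit Optional `"coef_fit"`; adds the selected-variable count.
#' @return An `"evaluation_report"` list with `r2`, `rmse`, `mae`, `n`,
#'   and (when `fit` is given) `zj` and `selected_names`.
#' @export
evaluate_predictions <- function(y, yhat, fit = NULL) {
  out <- list(r2 = r_squared(y, yhat), rmse = rmse(y, yhat),
              mae = mae(y, yhat), n = length(y))
  if (!is.null(fit)) {
    cs <- count_selected(fit)
    out$zj <- cs$count
    out$selected_names <- cs$names
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d  R2 = %.3f  RMSE = %.3f  MAE = %.3f",
              x$n, x$r2, x$rmse, x$mae))
  if (!is.null(x$zj)) cat("  ZJ =", x$zj)
  cat("\n")
  invisible(x)
}
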