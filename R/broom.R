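# tidy()/glance() methods for the fitted-result classes.

#' Tidy a pooled meta-analysis result
#'
#' One row per study plus the pooled row, in forest-plot order.
#'
#' @param x An `fm_meta` object.
#' @param ... Unused.
#' @return A tibble with `label`, `effect`, `ci_low`, `ci_high`, `weight`,
#'   `row_type`.
#' @export
tidy.fm_meta <- function(x, ...) {
  fd <- forest_data(x)
  attr(fd, "caption") <- NULL
  fd
}

#' One-row summary of a pooled meta-analysis
#'
#' @param x An `fm_meta` object.
#' @param ... Unused.
#' @return One-row tibble with the pooled estimate, interval, heterogeneity
#'   statistics and estimator.
#' @export
glance.fm_meta <- function(x, ...) {
  tibble(
    pooled = x$pooled, ci_low = x$ci_low, ci_high = x$ci_high,
    q = x$q, df = x$df, p_heterogeneity = x$p_heterogeneity,
    tau2 = x$tau2, i2_percent = x$i2_percent, method = x$method,
    n_studies = nrow(x$studies)
  )
}

#' Tidy a combined spline-logistic model fit
#'
#' Coefficients of the logistic fit on the spline bases.
#'
#' @param x An `fm_combined_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.fm_combined_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(
    term = rownames(co), estimate = co[, 1], std_error = co[, 2],
    statistic = co[, 3], p_value = co[, 4]
  )
}

#' One-row summary of a combined model fit
#'
#' @param x An `fm_combined_fit`.
#' @param ... Unused.
#' @return One-row tibble: apparent AUC with DeLong interval, group sizes,
#'   deviance, AIC, separation flag.
#' @export
glance.fm_combined_fit <- function(x, ...) {
  tibble(
    auc = x$roc$auc, ci_low = x$roc$ci_low, ci_high = x$roc$ci_high,
    n_pos = x$roc$n_pos, n_neg = x$roc$n_neg, n = x$n,
    deviance = x$fit$deviance, aic = x$fit$aic, separation = x$separation
  )
}
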