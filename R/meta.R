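# Random-effects meta-analysis of study-level AUCs: standard errors recovered
# from printed confidence intervals, Cochran's Q, DerSimonian-Laird and REML
# tau-squared, pooled estimate with normal-theory interval, and forest-plot
# data. Effects are pooled on the raw AUC scale (the printed summary
# intervals are symmetric around the pooled AUC, consistent with raw-scale
# pooling).

#' Standard error from a printed confidence interval
#'
#' `(ci_high - ci_low) / (2 z)`, with `z` the exact standard-normal quantile
#' at `(1 + level) / 2` (not the rounded 1.96).
#'
#' @param estimate Point estimate (must lie inside the interval).
#' @param ci_low,ci_high Interval bounds.
#' @param level Coverage of the interval (default 0.95).
#' @return Positive standard error.
#' @export
#' @examples
#' se_from_ci(0.77, 0.72, 0.82)  # 0.02551
se_from_ci <- function(estimate, ci_low, ci_high, level = 0.95) {
  if (level <= 0 || level >= 1) abort("se_from_ci: level must be in (0,1)")
  if (any(ci_low > estimate | estimate > ci_high)) {
    abort("se_from_ci: interval must bracket the estimate")
  }
  se <- (ci_high - ci_low) / (2 * qnorm((1 + level) / 2))
  if (any(se <= 0)) {
    abort("se_from_ci: zero-width interval gives se = 0; meta-analytic weights undefined")
  }
  se
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_i (y_i - yhat)^2` with inverse-variance weights `w_i = 1/se_i^2`
#' and `yhat` the fixed-effect weighted mean; `df = k - 1`.
#'
#' @param effect Study effects.
#' @param se Study standard errors.
#' @return List with `q`, `df`, and the fixed-effect mean `fe`.
#' @export
cochran_q <- function(effect, se) {
  if (length(effect) != length(se)) abort("cochran_q: length mismatch")
  if (any(se <= 0)) abort("cochran_q: standard errors must be positive")
  if (length(effect) < 2) {
    warn("cochran_q: fewer than 2 studies; Q = 0, df = 0")
    return(list(q = 0, df = 0L, fe = effect[1] %||% NA_real_))
  }
  w <- 1 / se^2
  fe <- sum(w * effect) / sum(w)
  list(q = sum(w * (effect - fe)^2), df = length(effect) - 1L, fe = fe)
}

#' Between-study variance estimate
#'
#' DerSimonian-Laird: `max(0, (Q - df) / C)` with
#' `C = sum(w) - sum(w^2)/sum(w)`. REML: iterative maximisation of the
#' restricted likelihood (root of its score in tau-squared, bracketed and
#' solved to relative tolerance 1e-8), floored at zero; failure to bracket the
#' root within `max_iter` doublings of the search interval is an error
#' reporting the last iterate.
#'
#' @param effect,se Study effects and standard errors.
#' @param method `"DL"` or `"REML"`.
#' @param max_iter,tol REML iteration controls.
#' @return Non-negative tau-squared.
#' @export
tau2_estimate <- function(effect, se, method = c("DL", "REML"),
                          max_iter = 100, tol = 1e-8) {
  method <- match.arg(method)
  v <- se^2
  w <- 1 / v
  qq <- cochran_q(effect, se)
  if (method == "DL") {
    C <- sum(w) - sum(w^2) / sum(w)
    return(max(0, (qq$q - qq$df) / C))
  }
  # score of the restricted log-likelihood in tau2 (profiled over the mean)
  score <- function(tau2) {
    wi <- 1 / (v + tau2)
    mu <- sum(wi * effect) / sum(wi)
    -0.5 * sum(wi) + 0.5 * sum(wi^2) / sum(wi) +
      0.5 * sum(wi^2 * (effect - mu)^2)
  }
  # monotone decreasing score: a non-positive value at zero means the
  # restricted likelihood is maximised at the boundary; DL and REML then
  # agree when the data are under-dispersed
  if (score(0) <= 0) return(0)
  upper <- max((qq$q - qq$df) / (sum(w) - sum(w^2) / sum(w)), tol)
  it <- 0
  while (score(upper) > 0) {
    upper <- upper * 2
    it <- it + 1
    if (it > max_iter) {
      abort(sprintf(
        "tau2_estimate: REML score not bracketed after %d expansions (last tau2 = %g)",
        max_iter, upper
      ))
    }
  }
  root <- stats::uniroot(score, c(0, upper), tol = tol * max(upper, 1))
  max(0, root$root)
}

#' Random-effects pooling of study effects
#'
#' Pools per-study effects (here AUCs) with weights `1/(se^2 + tau2)`;
#' the confidence interval is `pooled +/- z / sqrt(sum(w*))`. Heterogeneity is
#' reported as Cochran's Q with its chi-square p-value and as I-squared in
#' both conventional definitions: Q-based `max(0, (Q - df)/Q) * 100` and
#' variance-based `tau2 / (tau2 + s2) * 100` with `s2` the typical
#' within-study variance `df * sum(w) / (sum(w)^2 - sum(w^2))`; the default
#' `i2_percent` matches the estimator (Q-based for DL, variance-based for
#' REML — the two coincide under DL).
#'
#' @param data Data frame of studies.
#' @param effect,se,label Column names of effects, standard errors and study
#'   labels (`label` optional).
#' @param method Tau-squared estimator, `"DL"` (default) or `"REML"`.
#' @param conf_level Confidence level.
#' @return List of class `fm_meta`: `pooled`, `ci_low`, `ci_high`, `q`, `df`,
#'   `p_heterogeneity`, `tau2`, `i2_percent`, `i2_q_percent`,
#'   `i2_tau2_percent`, `method`, `studies` (tibble of inputs with weights).
#' @export
#' @examples
#' studies <- tibble::tibble(label = c("A", "B"),
#'                           auc = c(0.6, 0.8), se = c(0.1, 0.1))
#' pool_random_effects(studies, effect = "auc", se = "se")
pool_random_effects <- function(data, effect = "auc", se = "se",
                                label = NULL, method = c("DL", "REML"),
                                conf_level = 0.95) {
  method <- match.arg(method)
  data <- as_tibble(data)
  y <- data[[effect]]
  s <- data[[se]]
  if (is.null(y) || is.null(s)) abort("pool_random_effects: missing columns")
  if (any(s <= 0)) abort("pool_random_effects: standard errors must be positive")
  labels <- if (!is.null(label)) as.character(data[[label]]) else
    paste0("study ", seq_along(y))
  k <- length(y)
  z <- qnorm((1 + conf_level) / 2)
  if (k < 2) {
    warn("pool_random_effects: single study returned unpooled")
    out <- list(
      pooled = y[1], ci_low = y[1] - z * s[1], ci_high = y[1] + z * s[1],
      q = 0, df = 0L, p_heterogeneity = NA_real_, tau2 = 0,
      i2_percent = 0, i2_q_percent = 0, i2_tau2_percent = 0,
      method = method, conf_level = conf_level,
      studies = tibble(label = labels, effect = y, se = s, weight = 1)
    )
    return(structure(out, class = "fm_meta"))
  }
  qq <- cochran_q(y, s)
  tau2 <- tau2_estimate(y, s, method = method)
  wstar <- 1 / (s^2 + tau2)
  pooled <- sum(wstar * y) / sum(wstar)
  se_pooled <- sqrt(1 / sum(wstar))
  w <- 1 / s^2
  s2_typical <- qq$df * sum(w) / (sum(w)^2 - sum(w^2))
  i2_q <- max(0, (qq$q - qq$df) / qq$q) * 100
  if (!is.finite(i2_q)) i2_q <- 0
  i2_tau2 <- tau2 / (tau2 + s2_typical) * 100
  structure(
    list(
      pooled = pooled,
      ci_low = pooled - z * se_pooled,
      ci_high = pooled + z * se_pooled,
      q = qq$q, df = qq$df,
      p_heterogeneity = pchisq(qq$q, qq$df, lower.tail = FALSE),
      tau2 = tau2,
      i2_percent = if (method == "DL") i2_q else i2_tau2,
      i2_q_percent = i2_q, i2_tau2_percent = i2_tau2,
      method = method, conf_level = conf_level,
      studies = tibble(
        label = labels, effect = y, se = s,
        weight = wstar / sum(wstar)
      )
    ),
    class = "fm_meta"
  )
}

#' @export
print.fm_meta <- function(x, ...) {
  cat("<fm_meta>", x$method, "random-effects model,",
      nrow(x$studies), "studies\n")
  cat(sprintf("  pooled %.4f (%.4f-%.4f)\n", x$pooled, x$ci_low, x$ci_high))
  cat(sprintf("  Q (df = %d) = %.4f, p = %.4f; tau2 = %.5f; I2 = %.2f%%\n",
              x$df, x$q, x$p_heterogeneity, x$tau2, x$i2_percent))
  invisible(x)
}

#' Forest-plot data for a pooled result
#'
#' Per-study rows (squares) followed by the pooled diamond row, plus caption
#' fields (Q, df, I-squared, heterogeneity p) as attributes, so a figure and
#' its machine-readable twin carry exactly the same numbers.
#'
#' @param result An `fm_meta` object.
#' @return Tibble with columns `label`, `effect`, `ci_low`, `ci_high`,
#'   `weight`, `row_type` (`study`/`pooled`), carrying a `caption` attribute.
#' @export
forest_data <- function(result) {
  stopifnot(inherits(result, "fm_meta"))
  z <- qnorm((1 + result$conf_level) / 2)
  rows <- bind_rows(
    result$studies |>
      mutate(
        ci_low = .data$effect - z * .data$se,
        ci_high = .data$effect + z * .data$se,
        row_type = "study"
      ) |>
      select("label", "effect", "ci_low", "ci_high", "weight", "row_type"),
    tibble(
      label = sprintf("RE model (%s)", result$method),
      effect = result$pooled, ci_low = result$ci_low,
      ci_high = result$ci_high, weight = 1, row_type = "pooled"
    )
  )
  attr(rows, "caption") <- list(
    q = result$q, df = result$df, i2_percent = result$i2_percent,
    tau2 = result$tau2, p_heterogeneity = result$p_heterogeneity
  )
  rows
}
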