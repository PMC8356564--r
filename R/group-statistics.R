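# Per-category descriptive summaries and the rank/correlation tests used to
# annotate the biomarker figures. All tests are two-sided; no multiple-testing
# correction is applied (none was used in the analyses these mirror).

#' Median and interquartile range by group
#'
#' One summary row per distinct group. Quartiles use linear interpolation
#' between order statistics ([stats::quantile()] type 7, the usual statistical
#' software default); reported IQRs depend on this convention.
#'
#' @param data Data frame.
#' @param value Name of the numeric value column.
#' @param group Name of the grouping column.
#' @param na_rm Drop missing values before summarising (per-group complete
#'   cases)?
#' @return Tibble with columns `group`, `n`, `median`, `q1`, `q3`.
#' @export
#' @examples
#' df <- tibble::tibble(g = "a", x = 1:5)
#' median_iqr_by_group(df, "x", "g")
median_iqr_by_group <- function(data, value, group, na_rm = TRUE) {
  data <- as_tibble(data)
  if (!value %in% names(data)) abort(sprintf("no column '%s'", value))
  if (!group %in% names(data)) abort(sprintf("no column '%s'", group))
  if (na_rm) data <- data |> filter(!is.na(.data[[value]]))
  if (nrow(data) == 0) abort("median_iqr_by_group: no non-missing values")
  data |>
    group_by(group = .data[[group]]) |>
    summarise(
      n = n(),
      median = median(.data[[value]]),
      q1 = unname(quantile(.data[[value]], 0.25, type = 7)),
      q3 = unname(quantile(.data[[value]], 0.75, type = 7)),
      .groups = "drop"
    )
}

# shared shape for test results
fm_test_result <- function(statistic, p_value, method, n_per_group,
                           estimate = NA_real_) {
  tibble(
    statistic = statistic, p_value = p_value, estimate = estimate,
    method = method, n_per_group = list(unname(n_per_group))
  )
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum (Mann-Whitney) test comparing two groups. The p-value is
#' exact (full enumeration) when both groups have at most `exact_max`
#' observations and the pooled data are tie-free; otherwise the normal
#' approximation with average-rank tie correction and, optionally, continuity
#' correction is used. The reported statistic is the rank sum of `x` with
#' average ranks for ties.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_max Per-group size at or below which the exact distribution is
#'   enumerated (given no ties).
#' @param correct Apply the continuity correction in the normal approximation?
#' @return One-row tibble: `statistic` (rank sum of `x`), `z` (normal
#'   approximation z-score, `NA` when the exact p was used), `p_value`,
#'   `method`, `n_per_group`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))  # exact p = 2/6
wilcoxon_rank_sum <- function(x, y, exact_max = 10, correct = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    abort("wilcoxon_rank_sum: empty group")
  }
  if (anyNA(x) || anyNA(y)) abort("wilcoxon_rank_sum: missing values")
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0
  exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = correct, alternative = "two.sided")
  )
  r <- rank(pooled)
  w1 <- sum(r[seq_along(x)])
  nx <- length(x); ny <- length(y)
  z <- NA_real_
  if (!exact) {
    # tie-corrected normal approximation for the Mann-Whitney U of x
    u <- w1 - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    nties <- table(pooled)
    n <- nx + ny
    sigma2 <- (nx * ny / 12) *
      ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
    cc <- if (correct) sign(u - mu) * 0.5 else 0
    z <- if (sigma2 > 0) (u - mu - cc) / sqrt(sigma2) else 0
  }
  out <- fm_test_result(
    statistic = w1, p_value = ht$p.value,
    method = if (exact) "Wilcoxon rank sum, exact" else
      "Wilcoxon rank sum, normal approximation",
    n_per_group = c(nx, ny)
  )
  out$z <- z
  out
}

#' Kruskal-Wallis test across k groups
#'
#' Tie-corrected H statistic referred to a chi-square distribution with k-1
#' degrees of freedom.
#'
#' @param data Data frame.
#' @param value,group Column names of values and group labels.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `method`,
#'   `n_per_group`.
#' @export
kruskal_wallis <- function(data, value, group) {
  data <- as_tibble(data) |> filter(!is.na(.data[[value]]))
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("kruskal_wallis: need at least 2 groups")
  ht <- kruskal.test(data[[value]], g)
  out <- fm_test_result(
    statistic = unname(ht$statistic), p_value = ht$p.value,
    method = "Kruskal-Wallis rank sum",
    n_per_group = as.integer(table(g))
  )
  out$df <- unname(ht$parameter)
  out
}

#' Spearman correlation along the bacterial-to-viral spectrum
#'
#' Rank correlation (average ranks for ties) between biomarker concentrations
#' and the spectrum ordinal 1 (definite bacterial) ... 7 (definite viral), the
#' OTHER group having been excluded upstream. Higher concentrations at the
#' bacterial end give negative rho. The p-value uses the t approximation
#' (ties make the exact distribution unavailable in general).
#'
#' @param values Numeric concentrations.
#' @param ordinals Integer spectrum positions ([spectrum_ordinal()]).
#' @return One-row tibble with `estimate` (rho), `statistic` (S), `p_value`.
#' @export
spearman_rho <- function(values, ordinals) {
  keep <- !is.na(values) & !is.na(ordinals)
  values <- as.numeric(values[keep]); ordinals <- as.numeric(ordinals[keep])
  if (length(values) < 3) abort("spearman_rho: need at least 3 paired values")
  if (length(unique(values)) < 2 || length(unique(ordinals)) < 2) {
    abort("spearman_rho: rho undefined for constant input")
  }
  ht <- suppressWarnings(
    cor.test(values, ordinals, method = "spearman", exact = FALSE)
  )
  fm_test_result(
    statistic = unname(ht$statistic), p_value = ht$p.value,
    method = "Spearman rank correlation",
    n_per_group = length(values), estimate = unname(ht$estimate)
  )
}

#' Pearson correlation between CRP and a biomarker
#'
#' @param x,y Numeric vectors of equal length (at least 3 complete pairs);
#'   missing pairs are dropped.
#' @return One-row tibble with `estimate` (r), `statistic` (t), `p_value`.
#' @export
pearson_r <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  if (length(x) < 3) abort("pearson_r: need at least 3 complete pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("pearson_r: non-finite values")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("pearson_r: zero variance")
  }
  ht <- cor.test(x, y, method = "pearson")
  fm_test_result(
    statistic = unname(ht$statistic), p_value = ht$p.value,
    method = "Pearson correlation",
    n_per_group = length(x), estimate = unname(ht$estimate)
  )
}
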