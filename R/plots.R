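# Figures: forest plots for pooled AUCs and per-category biomarker bar plots.
# Every figure has a machine-readable twin (forest_data(), median_iqr_by_group())
# containing exactly the plotted numbers.

#' Forest plot of a random-effects pooled AUC
#'
#' Per-study squares with 95% confidence whiskers and the pooled diamond,
#' captioned with the heterogeneity statistics (I-squared, Q, df, p).
#'
#' @param object An `fm_meta` result.
#' @param title Optional plot title.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fm_meta <- function(object, title = NULL, ...) {
  fd <- forest_data(object)
  cap <- attr(fd, "caption")
  fd <- fd |>
    mutate(
      label = factor(.data$label, levels = rev(.data$label)),
      row_type = factor(.data$row_type, levels = c("study", "pooled"))
    )
  ggplot2::ggplot(fd, ggplot2::aes(x = .data$effect, y = .data$label)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.15
    ) +
    ggplot2::geom_point(
      ggplot2::aes(shape = .data$row_type, size = .data$row_type)
    ) +
    ggplot2::scale_shape_manual(values = c(study = 15, pooled = 18),
                                guide = "none") +
    ggplot2::scale_size_manual(values = c(study = 3, pooled = 5),
                               guide = "none") +
    ggplot2::labs(
      x = "AUC", y = NULL, title = title,
      caption = sprintf(
        "I² = %.2f%%, Q (df = %d) = %.4f, p = %.4f",
        cap$i2_percent, cap$df, cap$q, cap$p_heterogeneity
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fm_meta
#' @param result An `fm_meta` result.
#' @export
plot_forest <- function(result, title = NULL) {
  autoplot.fm_meta(result, title = title)
}

#' Per-category biomarker bar plot
#'
#' Median bars with interquartile whiskers and jittered individual values per
#' analysis group, annotated with the overall Kruskal-Wallis p-value — the
#' style used to display biomarker concentrations across the phenotype
#' spectrum.
#'
#' @param data Patients tibble joined to a grouping column.
#' @param value Biomarker column name.
#' @param group Grouping column name (analysis group or SBI label).
#' @param jitter_max At most this many individual points are jittered (larger
#'   cohorts are down-sampled for legibility; medians/IQRs use all data).
#' @param seed Seed for the down-sampling and jitter.
#' @return A ggplot object.
#' @export
plot_biomarker_bars <- function(data, value, group, jitter_max = 2000,
                                seed = 1L) {
  data <- as_tibble(data) |> filter(!is.na(.data[[value]]))
  summ <- median_iqr_by_group(data, value, group)
  kw <- if (length(unique(data[[group]])) >= 2) {
    kruskal_wallis(data, value, group)
  } else {
    NULL
  }
  lv <- intersect(c(analysis_groups(), "SBI", "NON_SBI"),
                  unique(summ$group))
  if (length(lv) == 0) lv <- unique(summ$group)
  summ$group <- factor(summ$group, levels = lv)
  pts <- data
  set.seed(seed)
  if (nrow(pts) > jitter_max) {
    pts <- pts[sample.int(nrow(pts), jitter_max), , drop = FALSE]
  }
  pts$group <- factor(pts[[group]], levels = lv)
  subtitle <- if (!is.null(kw)) {
    sprintf("Kruskal-Wallis p = %.3g", kw$p_value)
  }
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$median)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$q1, ymax = .data$q3), width = 0.25
    ) +
    ggplot2::geom_jitter(
      data = pts, ggplot2::aes(x = .data$group, y = .data[[value]]),
      width = 0.2, alpha = 0.25, size = 0.6, colour = "grey40",
      inherit.aes = FALSE
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = value, subtitle = subtitle) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
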