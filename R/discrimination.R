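# ROC/AUC per biomarker and contrast, DeLong confidence intervals, and the
# combined three-biomarker restricted-cubic-spline logistic model.

#' Empirical AUC with DeLong confidence interval
#'
#' The AUC equals the Mann-Whitney statistic U/(n_pos * n_neg), ties counted
#' one half; the confidence interval uses the DeLong variance estimator,
#' truncated to [0, 1]. The positive class is the bacterial side of the
#' contrast (SBI, or definite bacterial), so AUC > 0.5 means the marker is
#' higher in bacterial illness.
#'
#' @param scores Numeric predictor values.
#' @param labels Class labels; coerced to factor. `positive` names the
#'   positive level.
#' @param positive Label of the positive (bacterial-side) class.
#' @param conf_level Confidence level of the DeLong interval.
#' @param contrast,predictor Optional annotations carried into the result.
#' @return One-row tibble of class `fm_roc`: `predictor`, `contrast`, `auc`,
#'   `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(3, 1, 2, 0), c("pos", "pos", "neg", "neg"), positive = "pos")
roc_auc <- function(scores, labels, positive = NULL, conf_level = 0.95,
                    contrast = NA_character_, predictor = NA_character_) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- as.numeric(scores[keep])
  labels <- as.character(labels[keep])
  lv <- unique(labels)
  if (length(lv) < 2) abort("roc_auc: need both classes present")
  if (length(lv) > 2) abort("roc_auc: more than two classes")
  if (is.null(positive)) positive <- sort(lv)[2]
  if (!positive %in% lv) abort("roc_auc: positive class absent")
  resp <- factor(labels == positive, levels = c(FALSE, TRUE))
  r <- pROC::roc(
    response = resp, predictor = scores, quiet = TRUE,
    direction = "<", levels = c("FALSE", "TRUE")
  )
  # at AUC = 1 the DeLong variance degenerates and the interval collapses;
  # that is expected behaviour here, not worth a warning per call
  ci <- as.numeric(withCallingHandlers(
    pROC::ci.auc(r, conf.level = conf_level, method = "delong"),
    warning = function(w) {
      if (grepl("always 1-1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  ))
  out <- tibble(
    predictor = predictor, contrast = contrast,
    auc = as.numeric(pROC::auc(r)),
    ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
    n_pos = sum(resp == "TRUE"), n_neg = sum(resp == "FALSE"),
    conf_level = conf_level
  )
  class(out) <- c("fm_roc", class(out))
  out
}

#' Restricted cubic spline basis
#'
#' Truncated-power construction of the restricted (natural) cubic spline
#' basis: k strictly increasing knots yield k-1 design columns, the first
#' being the identity (linear) term; the function is linear beyond the
#' boundary knots and has zero second derivative there. Nonlinear terms are
#' scaled by the square of the boundary-knot span, keeping columns on roughly
#' the scale of the data.
#'
#' @param values Numeric vector.
#' @param knots Strictly increasing numeric vector, length >= 3.
#' @return Matrix with `length(knots) - 1` columns (`linear`, `rcs1`, ...).
#' @export
rcs_basis <- function(values, knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3) abort("rcs_basis: need at least 3 knots")
  if (any(diff(knots) <= 0)) abort("rcs_basis: knots must be strictly increasing")
  x <- as.numeric(values)
  k <- length(knots)
  t1 <- knots[1]; tk <- knots[k]; tk1 <- knots[k - 1]
  norm <- (tk - t1)^2
  p3 <- function(u) pmax(u, 0)^3
  cols <- map(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (p3(x - tj) -
       p3(x - tk1) * (tk - tj) / (tk - tk1) +
       p3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  })
  out <- cbind(x, do.call(cbind, cols))
  colnames(out) <- c("linear", paste0("rcs", seq_len(k - 2)))
  out
}

default_knots <- function(x, n_knots = 3) {
  probs <- switch(as.character(n_knots),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    seq(0.05, 0.95, length.out = n_knots)
  )
  unname(quantile(x, probs, type = 7))
}

#' Combined spline-logistic biomarker model
#'
#' Fits a maximum-likelihood logistic regression of the bacterial-side label
#' on restricted-cubic-spline expansions of each listed biomarker (default 3
#' knots at the 10th/50th/90th percentiles of the complete-case data), and
#' reports the apparent (in-sample) AUC of the fitted probabilities with a
#' DeLong confidence interval. Records missing any listed biomarker are
#' dropped (complete cases across the panel). Biomarkers enter on the raw
#' concentration scale by default (the splines absorb skew); set
#' `log_scale = TRUE` to model log concentrations instead.
#'
#' @param data Patients tibble carrying biomarker columns and a label column.
#' @param outcome Name of the label column.
#' @param positive Positive (bacterial-side) level of the label.
#' @param predictors Biomarker names (short or column form).
#' @param n_knots Knots per predictor (>= 3).
#' @param log_scale Model log-transformed concentrations?
#' @param contrast Annotation carried into the ROC result.
#' @return List of class `fm_combined_fit`: `roc` (an `fm_roc` row), `fit`
#'   (the `glm`), `knots` (per-predictor knot vectors), `separation` flag,
#'   `n`.
#' @export
fit_combined_model <- function(data, outcome, positive,
                               predictors = c("PCT", "NGAL", "resistin"),
                               n_knots = 3, log_scale = FALSE,
                               contrast = NA_character_) {
  if (n_knots < 3) abort("fit_combined_model: need at least 3 knots")
  data <- as_tibble(data)
  cols <- map_chr(predictors, fm_biomarker_column)
  miss <- setdiff(c(cols, outcome), names(data))
  if (length(miss) > 0) {
    abort(sprintf("fit_combined_model: missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  cc <- stats::complete.cases(data[, c(cols, outcome)])
  data <- data[cc, , drop = FALSE]
  y <- data[[outcome]] == positive
  if (length(unique(y)) < 2) {
    abort("fit_combined_model: both outcome classes must be present")
  }
  bases <- list(); knots_used <- list()
  for (i in seq_along(cols)) {
    x <- data[[cols[i]]]
    if (log_scale) x <- log(x + .Machine$double.eps)
    kn <- default_knots(x, n_knots)
    if (any(diff(kn) <= 0)) {
      abort(sprintf(
        "fit_combined_model: predictor '%s' has fewer distinct values than knots",
        predictors[i]
      ))
    }
    b <- rcs_basis(x, kn)
    colnames(b) <- paste0(predictors[i], "_", colnames(b))
    bases[[i]] <- b
    knots_used[[predictors[i]]] <- kn
  }
  X <- as.data.frame(do.call(cbind, bases))
  df <- cbind(data.frame(.y = y), X)
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      # extreme fitted probabilities are routine with heavy-tailed markers;
      # actual separation is detected below from the fit itself
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  prob <- as.numeric(predict(fit, type = "response"))
  separation <- fit$deviance < 1e-6 || min(prob[y]) > max(prob[!y])
  roc <- roc_auc(
    prob, if_else(y, positive, paste0("non-", positive)), positive = positive,
    contrast = contrast, predictor = paste(predictors, collapse = "+")
  )
  structure(
    list(roc = roc, fit = fit, knots = knots_used,
         separation = separation, n = nrow(df)),
    class = "fm_combined_fit"
  )
}

#' @export
print.fm_combined_fit <- function(x, ...) {
  cat("<fm_combined_fit>", x$roc$predictor, "\n")
  cat(sprintf("  n = %d, apparent AUC = %.3f (%.3f-%.3f)%s\n",
              x$n, x$roc$auc, x$roc$ci_low, x$roc$ci_high,
              if (x$separation) " [perfect separation flagged]" else ""))
  invisible(x)
}
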