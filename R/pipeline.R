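# Pipeline stages tying the modules into the full workflow:
# simulate -> classify -> evaluate -> meta. Each stage is re-runnable from
# its intermediates; a thin command-line front end over these functions ships
# in inst/cli/febrimark.R. Numeric outputs are never rounded internally;
# rounding to 2 decimals happens only in printed summaries.

fm_write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Pipeline stage 1: classify a cohort
#'
#' Reads (or takes) a cohort, runs the phenotype and SBI classifiers, writes
#' `categories.csv` (patient_id, perform_category, analysis_group, sbi_label,
#' spectrum_ordinal, audit_path, audit_flag) and logs category counts.
#'
#' @param cohort An `fm_cohort`, or the result of [read_cohort()].
#' @param out_dir Output directory; `NULL` to skip writing.
#' @param thresholds [classifier_thresholds()].
#' @param quiet Suppress the count log?
#' @return The classification tibble, invisibly when writing.
#' @export
run_classify <- function(cohort, out_dir = NULL,
                         thresholds = classifier_thresholds(),
                         quiet = FALSE) {
  cls <- classify_cohort(cohort$patients, cohort$findings, thresholds)
  if (!quiet) {
    counts <- cls |> count(.data$analysis_group, name = "n")
    message(paste(
      sprintf("%s: %d", counts$analysis_group, counts$n), collapse = "; "
    ))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cls, file.path(out_dir, "categories.csv"), na = "")
    return(invisible(cls))
  }
  cls
}

#' Pipeline stage 2: evaluate biomarkers against the classifications
#'
#' For each biomarker present in the cohort (complete cases per biomarker):
#' per-group median/IQR summaries over the eight analysis groups and the SBI
#' dichotomy; Wilcoxon rank-sum for definite bacterial vs definite viral and
#' for SBI vs non-SBI; Kruskal-Wallis across the analysis groups; Spearman
#' correlation along the seven-group spectrum (OTHER excluded); Pearson
#' correlation of log biomarker with log CRP; ROC AUCs with DeLong intervals
#' for both contrasts; and, when all three panel biomarkers are present, the
#' combined spline-logistic model per contrast. Contrast groups that are
#' empty are skipped with a warning.
#'
#' @param cohort An `fm_cohort`.
#' @param classifications Output of [run_classify()] for the same cohort.
#' @param out_dir Optional output directory: writes `stats.json`, `roc.csv`,
#'   `summaries.csv` and one bar-plot PNG per biomarker/grouping.
#' @param n_knots Knots per predictor in the combined model.
#' @param seed Seed for plot jitter only.
#' @return List with elements `summaries`, `tests`, `roc`, `combined`.
#' @export
run_evaluate <- function(cohort, classifications, out_dir = NULL,
                         n_knots = 3, seed = 1L) {
  data <- cohort$patients |>
    left_join(classifications, by = "patient_id")
  markers <- names(FM_BIOMARKERS)[
    map_lgl(FM_BIOMARKERS, ~ .x %in% names(data) && any(!is.na(data[[.x]])))
  ]
  summaries <- list(); tests <- list(); rocs <- list()

  contrast_sets <- function(d, col) {
    list(
      DB_vs_DV = list(
        pos = d |> filter(.data$analysis_group == "DEFINITE_BACTERIAL"),
        neg = d |> filter(.data$analysis_group == "DEFINITE_VIRAL")
      ),
      SBI_vs_nonSBI = list(
        pos = d |> filter(.data$sbi_label == "SBI"),
        neg = d |> filter(.data$sbi_label == "NON_SBI")
      )
    )
  }

  for (m in markers) {
    col <- FM_BIOMARKERS[[m]]
    d <- complete_cases(data, m)
    summaries[[paste0(m, "_perform")]] <-
      median_iqr_by_group(d, col, "analysis_group") |>
      mutate(biomarker = m, grouping = "perform")
    summaries[[paste0(m, "_sbi")]] <-
      median_iqr_by_group(d, col, "sbi_label") |>
      mutate(biomarker = m, grouping = "sbi")

    tst <- list()
    if (length(unique(d$analysis_group)) >= 2) {
      tst$kruskal_wallis <- kruskal_wallis(d, col, "analysis_group")
    }
    spect <- d |> filter(!is.na(.data$spectrum_ordinal))
    if (nrow(spect) >= 3 &&
        length(unique(spect$spectrum_ordinal)) >= 2 &&
        length(unique(spect[[col]])) >= 2) {
      tst$spearman_spectrum <- spearman_rho(spect[[col]],
                                            spect$spectrum_ordinal)
    }
    crp_ok <- !is.na(d$crp_mg_per_l) & d$crp_mg_per_l > 0 & d[[col]] > 0
    if (sum(crp_ok) >= 3) {
      tst$pearson_log_crp <- pearson_r(log(d[[col]][crp_ok]),
                                       log(d$crp_mg_per_l[crp_ok]))
    }
    for (ct in names(contrast_sets(d, col))) {
      cs <- contrast_sets(d, col)[[ct]]
      if (nrow(cs$pos) == 0 || nrow(cs$neg) == 0) {
        warn(sprintf("%s %s: empty contrast group, skipped", m, ct))
        next
      }
      tst[[paste0("wilcoxon_", ct)]] <-
        wilcoxon_rank_sum(cs$pos[[col]], cs$neg[[col]])
      rocs[[paste0(m, "_", ct)]] <- roc_auc(
        c(cs$pos[[col]], cs$neg[[col]]),
        rep(c("pos", "neg"), c(nrow(cs$pos), nrow(cs$neg))),
        positive = "pos", contrast = ct, predictor = m
      )
    }
    tests[[m]] <- tst
  }

  combined <- list()
  if (all(c("PCT", "NGAL", "resistin") %in% markers)) {
    for (spec in list(
      list(ct = "DB_vs_DV", outcome = "analysis_group",
           positive = "DEFINITE_BACTERIAL",
           keep = c("DEFINITE_BACTERIAL", "DEFINITE_VIRAL")),
      list(ct = "SBI_vs_nonSBI", outcome = "sbi_label", positive = "SBI",
           keep = c("SBI", "NON_SBI"))
    )) {
      dd <- data |> filter(.data[[spec$outcome]] %in% spec$keep)
      dd <- dd[stats::complete.cases(dd[, unname(FM_BIOMARKERS)]), ]
      if (length(unique(dd[[spec$outcome]])) == 2) {
        combined[[spec$ct]] <- fit_combined_model(
          dd, outcome = spec$outcome, positive = spec$positive,
          n_knots = n_knots, contrast = spec$ct
        )
      } else {
        warn(sprintf("combined model %s: empty contrast group, skipped",
                     spec$ct))
      }
    }
  }

  summaries <- list_rbind(summaries)
  roc <- if (length(rocs) > 0) list_rbind(map(rocs, as_tibble)) else tibble()
  out <- list(summaries = summaries, tests = tests, roc = roc,
              combined = combined)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(summaries, file.path(out_dir, "summaries.csv"), na = "")
    roc_out <- bind_rows(
      roc,
      list_rbind(map(combined, ~ as_tibble(.x$roc)))
    )
    readr::write_csv(roc_out, file.path(out_dir, "roc.csv"), na = "")
    fm_write_json(
      list(
        tests = map(tests, ~ map(.x, function(t) {
          as.list(t |> select(-"n_per_group"))
        })),
        roc = roc_out,
        combined = map(combined, ~ as.list(glance(.x)))
      ),
      file.path(out_dir, "stats.json")
    )
    for (m in markers) {
      p <- plot_biomarker_bars(
        complete_cases(data, m), FM_BIOMARKERS[[m]], "analysis_group",
        seed = seed
      )
      ggplot2::ggsave(
        file.path(out_dir, sprintf("bars_%s.png", m)), p,
        width = 7, height = 4.5, dpi = 150, device = "png"
      )
    }
  }
  out
}

#' Pipeline stage 3: meta-analyse study-level AUCs
#'
#' Pools every (biomarker, contrast) group of the AUC table with at least two
#' studies using the random-effects model (standard errors recovered from the
#' printed 95% intervals); single-study groups are emitted unpooled with a
#' warning. Optionally writes `meta_result.json` and a forest PNG per group.
#'
#' @param auc_table Tibble from [read_auc_table()], or a path to one.
#' @param out_dir Optional output directory.
#' @param method Tau-squared estimator, `"DL"` or `"REML"`.
#' @return Named list of `fm_meta` results (`biomarker.contrast`).
#' @export
run_meta <- function(auc_table, out_dir = NULL, method = c("DL", "REML")) {
  method <- match.arg(method)
  if (is.character(auc_table)) auc_table <- read_auc_table(auc_table)
  groups <- auc_table |> distinct(.data$biomarker, .data$contrast)
  results <- list()
  for (i in seq_len(nrow(groups))) {
    rows <- auc_table |>
      filter(.data$biomarker == groups$biomarker[i],
             .data$contrast == groups$contrast[i]) |>
      mutate(se = se_from_ci(.data$auc, .data$ci_low, .data$ci_high))
    key <- paste(groups$biomarker[i], groups$contrast[i], sep = ".")
    results[[key]] <- withCallingHandlers(
      pool_random_effects(rows, effect = "auc", se = "se", label = "study",
                          method = method),
      warning = function(w) {
        warn(sprintf("%s: %s", key, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fm_write_json(
      map(results, function(r) {
        c(glance(r) |> as.list(), list(studies = r$studies))
      }),
      file.path(out_dir, "meta_result.json")
    )
    for (key in names(results)) {
      ggplot2::ggsave(
        file.path(out_dir, sprintf("forest_%s.png", gsub("[^A-Za-z0-9_.]", "_", key))),
        autoplot(results[[key]], title = key),
        width = 6, height = 3.5, dpi = 150, device = "png"
      )
    }
  }
  results
}

#' Pipeline stage 0: simulate a synthetic cohort
#'
#' Generates a cohort from a configuration (or preset name), writes
#' `patients.csv` and `microbiology.csv` plus a sidecar provenance file
#' recording the configuration and seed.
#'
#' @param config An `fm_cohort_config`, or a preset name
#'   (see [preset_names()]).
#' @param out_dir Optional output directory.
#' @param seed Master seed for all generator randomness.
#' @return The generated `fm_cohort`.
#' @export
run_simulate <- function(config, out_dir = NULL, seed = 1L) {
  if (is.character(config)) config <- preset_cohort_config(config)
  cohort <- generate_cohort(config, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, out_dir)
    write_cohort_config(config, file.path(out_dir, "config.yaml"))
    fm_write_json(
      list(cohort_id = config$cohort_id, seed = seed,
           n = nrow(cohort$patients), generated = TRUE),
      file.path(out_dir, "provenance.json")
    )
  }
  cohort
}
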