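# Reading, validating and writing patient-level cohort tables and
# study-level AUC tables. Missing values are an empty field or "NA" on read,
# empty on write; encoding is UTF-8 and the decimal point is ".".

FM_PATIENT_COLUMNS <- c(
  "patient_id", "cohort_id", "age_months", "syndrome", "syndrome_suggests",
  "imaging_bacterial", "crp_mg_per_l", "pct_ug_per_l", "ngal_ng_per_ml",
  "resistin_ng_per_ml", "inflammatory_suspected", "trivial_illness",
  "distinct_other_infection"
)

FM_FINDING_COLUMNS <- c(
  "patient_id", "pathogen_name", "pathogen_class", "specimen_site",
  "site_sterile", "method", "clinically_consistent"
)

# CSV reader with per-column types applied only to the columns the file
# actually has; unknown columns are guessed and preserved as opaque extras
fm_read_csv <- function(path, types) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  spec <- do.call(
    readr::cols,
    c(as.list(types[intersect(names(types), header)]),
      .default = readr::col_guess())
  )
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                  progress = FALSE, col_types = spec)
}

#' Read a patient-level cohort from delimited text
#'
#' Loads a two-file cohort: a patients table (one row per child) and a long
#' microbiology table (one row per pathogen finding, zero or more per child),
#' joins them by `patient_id` and validates both against the schema. Unknown
#' columns are preserved as opaque extras.
#'
#' @param patients_path CSV file of patient records.
#' @param microbiology_path CSV file of microbiology findings; `NULL` for a
#'   cohort with no positive microbiology.
#' @param thresholds [classifier_thresholds()], for the sterile-site list.
#' @return An object of class `fm_cohort`: a list with tibbles `patients` and
#'   `findings` plus `cohort_id` and `provenance`.
#' @export
read_cohort <- function(patients_path, microbiology_path = NULL,
                        thresholds = classifier_thresholds()) {
  patients <- fm_read_csv(
    patients_path,
    types = c(
      patient_id = "c", cohort_id = "c", syndrome = "c",
      syndrome_suggests = "c", distinct_other_infection = "c",
      age_months = "d", crp_mg_per_l = "d", pct_ug_per_l = "d",
      ngal_ng_per_ml = "d", resistin_ng_per_ml = "d",
      imaging_bacterial = "l", inflammatory_suspected = "l",
      trivial_illness = "l"
    )
  )
  patients <- validate_patients(patients)
  findings <- NULL
  if (!is.null(microbiology_path)) {
    findings <- fm_read_csv(
      microbiology_path,
      types = c(
        patient_id = "c", pathogen_name = "c", pathogen_class = "c",
        specimen_site = "c", method = "c", site_sterile = "l",
        clinically_consistent = "l"
      )
    )
  }
  findings <- validate_findings(findings, patients, thresholds)
  new_cohort(
    patients, findings,
    cohort_id = patients$cohort_id[1] %||% NA_character_,
    provenance = paste0("read_cohort(", patients_path, ")")
  )
}

new_cohort <- function(patients, findings, cohort_id = NA_character_,
                       provenance = NA_character_) {
  structure(
    list(patients = patients, findings = findings,
         cohort_id = cohort_id, provenance = provenance),
    class = "fm_cohort"
  )
}

#' @export
print.fm_cohort <- function(x, ...) {
  cat("<fm_cohort>", if (!is.na(x$cohort_id)) x$cohort_id, "\n")
  cat("  patients:", nrow(x$patients), " findings:", nrow(x$findings), "\n")
  invisible(x)
}

#' Write a cohort back to delimited text
#'
#' Writes `patients.csv` and `microbiology.csv` in canonical column order
#' (schema columns first, extras after); missing values are written as empty
#' fields so a read-then-write cycle round-trips content.
#'
#' @param cohort An `fm_cohort` (or a list with `patients`/`findings`).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  canonical <- function(df, schema) {
    df[, c(intersect(schema, names(df)), setdiff(names(df), schema)),
       drop = FALSE]
  }
  pp <- file.path(dir, "patients.csv")
  mp <- file.path(dir, "microbiology.csv")
  readr::write_csv(canonical(cohort$patients, FM_PATIENT_COLUMNS), pp, na = "")
  readr::write_csv(canonical(cohort$findings, FM_FINDING_COLUMNS), mp, na = "")
  invisible(c(patients = pp, microbiology = mp))
}

#' Restrict a cohort to records with the named biomarker measured
#'
#' Implements the complete-case policy: each biomarker analysis uses only the
#' records where that biomarker was measured. Selection is per biomarker
#' (pairwise, not listwise), never mutates its input, and is idempotent.
#'
#' @param data A patients tibble or an `fm_cohort`.
#' @param biomarker One of `"PCT"`, `"NGAL"`, `"resistin"` (or the
#'   corresponding column name).
#' @return Object of the same shape as `data`, subset to complete cases.
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   patient_id = c("a", "b", "c"),
#'   syndrome = "fever_no_source", syndrome_suggests = "neither",
#'   pct_ug_per_l = c(0.2, NA, 1.4)
#' )
#' complete_cases(pts, "PCT")
complete_cases <- function(data, biomarker) {
  col <- fm_biomarker_column(biomarker)
  if (inherits(data, "fm_cohort")) {
    kept <- complete_cases(data$patients, biomarker)
    out <- new_cohort(
      kept,
      data$findings |> filter(.data$patient_id %in% kept$patient_id),
      cohort_id = data$cohort_id, provenance = data$provenance
    )
    return(out)
  }
  data <- as_tibble(data)
  if (!col %in% names(data)) {
    abort(sprintf("column '%s' is absent from this cohort", col))
  }
  data |> filter(!is.na(.data[[col]]))
}

#' Read a study-level AUC table
#'
#' Reads a delimited table of per-cohort AUC estimates with 95% confidence
#' intervals (columns `study`, `contrast`, `biomarker`, `auc`, `ci_low`,
#' `ci_high`) and validates that every CI brackets its estimate inside (0, 1).
#' The package ships a fixture transcribing the five published cohorts'
#' per-biomarker AUCs verbatim (see [table4_auc_path()]).
#'
#' @param path CSV file.
#' @return Validated tibble of study rows (possibly zero rows).
#' @export
read_auc_table <- function(path) {
  rows <- readr::read_csv(
    path, show_col_types = FALSE, na = c("", "NA"), progress = FALSE
  )
  need <- c("study", "contrast", "biomarker", "auc", "ci_low", "ci_high")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0) {
    abort(sprintf("auc table: missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (nrow(rows) == 0) {
    return(as_tibble(rows))
  }
  bad <- setdiff(unique(rows$contrast), c("SBI_vs_nonSBI", "DB_vs_DV"))
  if (length(bad) > 0) {
    abort(sprintf("auc table: invalid contrast value(s): %s",
                  paste(bad, collapse = ", ")))
  }
  ok <- with(rows, is.finite(auc) & is.finite(ci_low) & is.finite(ci_high) &
               ci_low > 0 & ci_high < 1 & ci_low <= auc & auc <= ci_high)
  if (!all(ok)) {
    abort(sprintf(
      "auc table: CI does not bracket the estimate inside (0,1) in row(s) %s",
      paste(which(!ok), collapse = ", ")
    ))
  }
  as_tibble(rows)
}

#' Packaged study-level AUC fixtures
#'
#' Paths to the packaged per-cohort AUC tables: the verbatim transcription of
#' the published table, and a corrected variant in which the one apparently
#' mistyped confidence bound (combined-model SBI contrast, Alder Hey ED:
#' upper bound 0.84 printed for an estimate of 0.71 with lower bound 0.67) is
#' replaced by the symmetric value 0.74. Both files are clearly labelled;
#' analyses default to the verbatim table.
#'
#' @param corrected Use the corrected variant?
#' @return File path.
#' @export
table4_auc_path <- function(corrected = FALSE) {
  fn <- if (corrected) "table4_auc_corrected.csv" else "table4_auc.csv"
  system.file("extdata", fn, package = "febrimark", mustWork = TRUE)
}
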