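# Eleven-category phenotype, its eight-group analysis collapse, the
# dichotomous SBI reference standard, and the bacterial->viral spectrum
# ordinal.

#' Category levels of the phenotype classification
#'
#' `perform_categories()` returns the eleven phenotype categories in
#' bacterial-to-viral spectrum order (the four non-infection categories last);
#' `analysis_groups()` the eight analysis groups after collapsing the four
#' non-infection categories into `OTHER`.
#'
#' @return Character vector of category names.
#' @export
perform_categories <- function() {
  c(
    "DEFINITE_BACTERIAL", "PROBABLE_BACTERIAL", "BACTERIAL_SYNDROME",
    "UNKNOWN", "VIRAL_SYNDROME", "PROBABLE_VIRAL", "DEFINITE_VIRAL",
    "TRIVIAL", "OTHER_INFECTION", "INFECTION_OR_INFLAMMATION",
    "INFLAMMATORY_SYNDROME"
  )
}

#' @rdname perform_categories
#' @export
analysis_groups <- function() {
  c(
    "DEFINITE_BACTERIAL", "PROBABLE_BACTERIAL", "BACTERIAL_SYNDROME",
    "UNKNOWN", "VIRAL_SYNDROME", "PROBABLE_VIRAL", "DEFINITE_VIRAL",
    "OTHER"
  )
}

FM_SYNDROMES <- c(
  "pneumonia", "urinary_tract_infection", "sepsis", "meningitis",
  "skin_soft_tissue", "bone_joint", "upper_respiratory", "bronchiolitis",
  "gastroenteritis", "fever_no_source", "other"
)

# syndromes that, when clinically adjudicated bacterial, constitute a
# clinical bacterial diagnosis for the SBI reference standard
FM_BACTERIAL_SYNDROMES <- c(
  "pneumonia", "urinary_tract_infection", "sepsis", "meningitis",
  "skin_soft_tissue", "bone_joint"
)

#' Validate a patient table
#'
#' Checks the patient-level schema: mandatory columns, enum values, uniqueness
#' of `patient_id`, and non-negative finite biomarker/CRP values where present.
#' Optional columns (`imaging_bacterial`, `crp_mg_per_l`, the three
#' biomarkers, `distinct_other_infection`, `cohort_id`, `age_months`) are added
#' as missing when absent; the boolean flags `inflammatory_suspected` and
#' `trivial_illness` default to `FALSE`.
#'
#' @param patients Data frame of patient records, one row per child.
#' @return The validated tibble with all schema columns present.
#' @export
validate_patients <- function(patients) {
  patients <- as_tibble(patients)
  for (col in c("patient_id", "syndrome", "syndrome_suggests")) {
    if (!col %in% names(patients)) {
      abort(sprintf("patients: mandatory column '%s' is missing", col))
    }
  }
  if (anyDuplicated(patients$patient_id)) {
    dup <- unique(patients$patient_id[duplicated(patients$patient_id)])
    abort(sprintf(
      "patients: duplicate patient_id: %s",
      paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  if (anyNA(patients$patient_id) || any(!nzchar(patients$patient_id))) {
    abort("patients: patient_id must be non-missing and non-empty")
  }
  bad <- setdiff(unique(patients$syndrome), FM_SYNDROMES)
  if (length(bad) > 0) {
    abort(sprintf("patients: invalid syndrome value(s): %s",
                  paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(patients$syndrome_suggests),
                 c("bacterial", "viral", "neither", "either"))
  if (length(bad) > 0 || anyNA(patients$syndrome_suggests)) {
    abort(sprintf("patients: invalid syndrome_suggests value(s): %s",
                  paste(c(bad, if (anyNA(patients$syndrome_suggests)) "NA"),
                        collapse = ", ")))
  }
  defaults <- list(
    cohort_id = NA_character_, age_months = NA_real_,
    imaging_bacterial = NA, crp_mg_per_l = NA_real_,
    pct_ug_per_l = NA_real_, ngal_ng_per_ml = NA_real_,
    resistin_ng_per_ml = NA_real_, distinct_other_infection = NA_character_,
    inflammatory_suspected = FALSE, trivial_illness = FALSE
  )
  for (col in names(defaults)) {
    if (!col %in% names(patients)) {
      patients[[col]] <- defaults[[col]]
    }
  }
  patients$inflammatory_suspected[is.na(patients$inflammatory_suspected)] <- FALSE
  patients$trivial_illness[is.na(patients$trivial_illness)] <- FALSE
  for (col in c("crp_mg_per_l", unname(FM_BIOMARKERS), "age_months")) {
    v <- patients[[col]]
    if (!is.numeric(v)) {
      abort(sprintf("patients: column '%s' must be numeric", col))
    }
    if (any(!is.na(v) & (!is.finite(v) | v < 0))) {
      abort(sprintf("patients: column '%s' has negative or non-finite values",
                    col))
    }
  }
  patients
}

#' Validate a microbiology findings table
#'
#' One row per pathogen finding; rows join to patients by `patient_id`.
#' `site_sterile`, when supplied, must agree with the configured sterile-site
#' list; when absent it is derived from the list. `clinically_consistent`
#' defaults to `FALSE` (expert adjudication is an input, never inferred).
#'
#' @param findings Data frame of microbiology findings (may be `NULL` or
#'   zero-row for a cohort without positive microbiology).
#' @param patients Validated patient table, used for referential integrity.
#' @param thresholds An [classifier_thresholds()] object supplying the
#'   sterile-site list.
#' @return Validated findings tibble.
#' @export
validate_findings <- function(findings, patients,
                              thresholds = classifier_thresholds()) {
  if (is.null(findings)) {
    findings <- tibble(
      patient_id = character(), pathogen_name = character(),
      pathogen_class = character(), specimen_site = character(),
      site_sterile = logical(), method = character(),
      clinically_consistent = logical()
    )
  }
  findings <- as_tibble(findings)
  for (col in c("patient_id", "pathogen_name", "pathogen_class",
                "specimen_site")) {
    if (!col %in% names(findings)) {
      abort(sprintf("findings: mandatory column '%s' is missing", col))
    }
  }
  if (!"method" %in% names(findings)) findings$method <- NA_character_
  if (!"clinically_consistent" %in% names(findings)) {
    findings$clinically_consistent <- FALSE
  }
  findings$clinically_consistent[is.na(findings$clinically_consistent)] <- FALSE
  if (nrow(findings) > 0) {
    bad <- setdiff(unique(findings$pathogen_class),
                   c("bacterial", "viral", "other"))
    if (length(bad) > 0) {
      abort(sprintf("findings: invalid pathogen_class value(s): %s",
                    paste(bad, collapse = ", ")))
    }
    bad <- setdiff(stats::na.omit(unique(findings$method)),
                   c("culture", "PCR", "antigen", "serology"))
    if (length(bad) > 0) {
      abort(sprintf("findings: invalid method value(s): %s",
                    paste(bad, collapse = ", ")))
    }
    if (anyNA(findings$specimen_site) || any(!nzchar(findings$specimen_site))) {
      abort("findings: specimen_site must be non-empty")
    }
    orphan <- setdiff(findings$patient_id, patients$patient_id)
    if (length(orphan) > 0) {
      abort(sprintf("findings: patient_id not present in patients: %s",
                    paste(utils::head(orphan, 5), collapse = ", ")))
    }
    sterile <- findings$specimen_site %in% thresholds$sterile_sites
    if (!"site_sterile" %in% names(findings)) {
      findings$site_sterile <- sterile
    } else {
      findings$site_sterile[is.na(findings$site_sterile)] <-
        sterile[is.na(findings$site_sterile)]
      clash <- findings$site_sterile != sterile
      if (any(clash)) {
        abort(sprintf(
          "findings: site_sterile contradicts the sterile-site list for site(s): %s",
          paste(unique(findings$specimen_site[clash]), collapse = ", ")
        ))
      }
    }
  } else if (!"site_sterile" %in% names(findings)) {
    findings$site_sterile <- logical()
  }
  findings
}

# Per-patient microbiology evidence flags used by both classifiers.
finding_flags <- function(patients, findings) {
  f <- findings |>
    group_by(.data$patient_id) |>
    summarise(
      has_sterile_bact = any(.data$pathogen_class == "bacterial" &
                               .data$site_sterile),
      has_consistent_nonsterile_bact =
        any(.data$pathogen_class == "bacterial" & !.data$site_sterile &
              .data$clinically_consistent),
      has_consistent_virus = any(.data$pathogen_class == "viral" &
                                   .data$clinically_consistent),
      has_virus = any(.data$pathogen_class == "viral"),
      n_findings = n(),
      .groups = "drop"
    )
  patients |>
    select("patient_id") |>
    left_join(f, by = "patient_id") |>
    mutate(
      across(c("has_sterile_bact", "has_consistent_nonsterile_bact",
               "has_consistent_virus", "has_virus"),
             ~ if_else(is.na(.x), FALSE, .x)),
      n_findings = if_else(is.na(.data$n_findings), 0L, .data$n_findings)
    )
}

# The rule tree for one patient, operating on precomputed scalar evidence
# flags. Returns category plus the ordered audit trail of nodes fired.
classify_one <- function(has_sterile_bact, has_consistent_nonsterile_bact,
                         has_consistent_virus, has_virus, n_findings,
                         trivial_illness, other_infection,
                         inflammatory_suspected, syndrome_suggests, crp,
                         crp_cut) {
  path <- character()
  node <- function(id, answer) path[[length(path) + 1L]] <<- paste0(id, "=", answer)
  done <- function(category, flag = NA_character_) {
    list(category = category,
         audit_path = paste(c(path, category), collapse = ";"),
         flag = flag)
  }
  # CRP decision node shared by the three branches that consult CRP; a missing
  # value resolves to UNKNOWN with an audit flag rather than an error
  crp_state <- function(id) {
    if (is.na(crp)) {
      node(id, "missing")
      "missing"
    } else if (crp >= crp_cut) {
      node(id, "high")
      "high"
    } else {
      node(id, "low")
      "low"
    }
  }

  if (has_sterile_bact) {
    node("sterile_site_bacterial", "yes")
    return(done("DEFINITE_BACTERIAL"))
  }
  node("sterile_site_bacterial", "no")

  if (trivial_illness) {
    node("trivial_illness", "yes")
    return(done("TRIVIAL"))
  }
  node("trivial_illness", "no")

  if (other_infection) {
    node("distinct_other_infection", "yes")
    return(done("OTHER_INFECTION"))
  }
  if (inflammatory_suspected) {
    node("inflammatory_suspected", "yes")
    if (n_findings > 0 || syndrome_suggests != "neither") {
      node("coexisting_infection_evidence", "yes")
      return(done("INFECTION_OR_INFLAMMATION"))
    }
    node("coexisting_infection_evidence", "no")
    return(done("INFLAMMATORY_SYNDROME"))
  }

  if (has_consistent_nonsterile_bact) {
    node("nonsterile_bacterial_consistent", "yes")
    st <- crp_state("crp_bacterial_isolate")
    if (st == "missing") return(done("UNKNOWN", "missing-CRP"))
    if (st == "high") return(done("PROBABLE_BACTERIAL"))
    # raised CRP absent: bacterial isolate alone is not enough; fall through
  }

  if (syndrome_suggests == "bacterial") {
    node("bacterial_phenotype", "yes")
    st <- crp_state("crp_bacterial_phenotype")
    if (st == "missing") return(done("UNKNOWN", "missing-CRP"))
    if (st == "high") return(done("BACTERIAL_SYNDROME"))
    return(done("UNKNOWN"))
  }

  if (syndrome_suggests == "viral") {
    node("viral_phenotype", "yes")
    st <- crp_state("crp_viral_phenotype")
    if (st == "missing") return(done("UNKNOWN", "missing-CRP"))
    if (st == "low") {
      if (has_consistent_virus) {
        node("virus_identified_consistent", "yes")
        return(done("DEFINITE_VIRAL"))
      }
      if (has_virus) {
        node("virus_identified", "yes")
        return(done("PROBABLE_VIRAL"))
      }
      node("virus_identified", "no")
      return(done("VIRAL_SYNDROME"))
    }
    # viral phenotype with unexplained raised CRP: viral syndrome when a
    # virus was found, otherwise unknown
    if (has_virus) {
      node("virus_identified", "yes")
      return(done("VIRAL_SYNDROME"))
    }
    node("virus_identified", "no")
    return(done("UNKNOWN"))
  }

  if (syndrome_suggests == "either" && has_consistent_virus) {
    node("virus_identified_either_phenotype", "yes")
    st <- crp_state("crp_viral_isolate")
    if (st == "missing") return(done("UNKNOWN", "missing-CRP"))
    if (st == "low") return(done("PROBABLE_VIRAL"))
    return(done("UNKNOWN"))
  }

  node("unclassified", "yes")
  done("UNKNOWN")
}

#' Classify a cohort on the eleven-category phenotype and the SBI standard
#'
#' Runs the deterministic rule tree over every patient: assigns the
#' eleven-category phenotype, the collapsed eight-group analysis label, the
#' dichotomous SBI reference label and the bacterial-to-viral spectrum ordinal,
#' and records the ordered rule nodes fired for each child so every
#' classification is auditable.
#'
#' A missing CRP value at a CRP decision node classifies as `UNKNOWN` with a
#' `missing-CRP` audit flag rather than raising an error. Sterile-site
#' bacterial detection dominates all other evidence, including co-detected
#' viruses.
#'
#' @param patients Patient table (see [validate_patients()]).
#' @param findings Microbiology findings table, zero or more rows per patient
#'   (see [validate_findings()]); `NULL` for none.
#' @param thresholds [classifier_thresholds()] object.
#' @return A tibble with one row per patient: `patient_id`,
#'   `perform_category`, `analysis_group`, `sbi_label`, `spectrum_ordinal`
#'   (`NA` for the OTHER group), `audit_path`, `audit_flag`.
#' @export
#' @examples
#' patients <- tibble::tibble(
#'   patient_id = c("a", "b"),
#'   syndrome = c("sepsis", "bronchiolitis"),
#'   syndrome_suggests = c("bacterial", "viral"),
#'   crp_mg_per_l = c(180, 12)
#' )
#' findings <- tibble::tibble(
#'   patient_id = c("a", "b"),
#'   pathogen_name = c("Streptococcus pneumoniae", "RSV"),
#'   pathogen_class = c("bacterial", "viral"),
#'   specimen_site = c("blood", "nasopharynx"),
#'   method = c("culture", "PCR"),
#'   clinically_consistent = c(TRUE, TRUE)
#' )
#' classify_cohort(patients, findings)
classify_cohort <- function(patients, findings = NULL,
                            thresholds = classifier_thresholds()) {
  stopifnot(inherits(thresholds, "fm_thresholds"))
  patients <- validate_patients(patients)
  findings <- validate_findings(findings, patients, thresholds)
  flags <- finding_flags(patients, findings)

  res <- pmap(
    list(
      flags$has_sterile_bact, flags$has_consistent_nonsterile_bact,
      flags$has_consistent_virus, flags$has_virus, flags$n_findings,
      patients$trivial_illness, !is.na(patients$distinct_other_infection),
      patients$inflammatory_suspected, patients$syndrome_suggests,
      patients$crp_mg_per_l
    ),
    function(sb, nb, cv, v, nf, triv, oth, infl, sugg, crp) {
      classify_one(sb, nb, cv, v, nf, triv, oth, infl, sugg, crp,
                   thresholds$crp_cut_mg_per_l)
    }
  )
  category <- map_chr(res, "category")
  group <- collapse_other(category)
  tibble(
    patient_id = patients$patient_id,
    perform_category = category,
    analysis_group = group,
    sbi_label = classify_sbi(patients, findings, thresholds),
    spectrum_ordinal = spectrum_ordinal(group),
    audit_path = map_chr(res, "audit_path"),
    audit_flag = map_chr(res, "flag")
  )
}

#' Eleven-category phenotype for each patient
#'
#' Vectorised convenience wrapper around [classify_cohort()] returning only
#' the phenotype category.
#'
#' @inheritParams classify_cohort
#' @return Character vector of categories, one per patient row.
#' @export
classify_perform <- function(patients, findings = NULL,
                             thresholds = classifier_thresholds()) {
  classify_cohort(patients, findings, thresholds)$perform_category
}

#' Dichotomous SBI reference label
#'
#' A child is labelled `SBI` when any of the following holds: bacterial
#' detection by culture or PCR in a sterile site (urine, CSF, blood, joint or
#' pleural fluid, bone); a clinically consistent bacterial isolate from a
#' non-sterile site with a compatible syndrome; bacterial-type changes on
#' imaging with a compatible syndrome (e.g., consolidation defining bacterial
#' pneumonia); or a clinical bacterial diagnosis (a bacterial-type syndrome
#' adjudicated bacterial without microbiological confirmation, e.g., abscess,
#' cellulitis). Otherwise `NON_SBI`.
#'
#' @inheritParams classify_cohort
#' @return Character vector, `"SBI"` or `"NON_SBI"`, one per patient row.
#' @export
classify_sbi <- function(patients, findings = NULL,
                         thresholds = classifier_thresholds()) {
  patients <- validate_patients(patients)
  findings <- validate_findings(findings, patients, thresholds)
  flags <- finding_flags(patients, findings)
  compatible_bacterial <-
    patients$syndrome_suggests %in% c("bacterial", "either") |
    patients$syndrome %in% FM_BACTERIAL_SYNDROMES
  clinical_bacterial <-
    patients$syndrome %in% FM_BACTERIAL_SYNDROMES &
    patients$syndrome_suggests == "bacterial"
  sbi <- flags$has_sterile_bact |
    (flags$has_consistent_nonsterile_bact & compatible_bacterial) |
    (!is.na(patients$imaging_bacterial) & patients$imaging_bacterial &
       compatible_bacterial) |
    clinical_bacterial
  if_else(sbi, "SBI", "NON_SBI")
}

#' Collapse the eleven categories into the eight analysis groups
#'
#' Identity on the seven infection categories; `TRIVIAL`, `OTHER_INFECTION`,
#' `INFECTION_OR_INFLAMMATION` and `INFLAMMATORY_SYNDROME` map to `OTHER`.
#'
#' @param category Character vector of phenotype categories.
#' @return Character vector of analysis groups.
#' @export
collapse_other <- function(category) {
  bad <- setdiff(unique(category), perform_categories())
  if (length(bad) > 0) {
    abort(sprintf("invalid phenotype category: %s", paste(bad, collapse = ", ")))
  }
  if_else(category %in% analysis_groups(), category, "OTHER")
}

#' Position on the bacterial-to-viral spectrum
#'
#' Maps the seven infection analysis groups to their ordinal position 1
#' (definite bacterial) through 7 (definite viral); `OTHER` is excluded from
#' the spectrum and maps to `NA`.
#'
#' @param group Character vector of analysis groups.
#' @return Integer vector (`NA` for `OTHER`).
#' @export
spectrum_ordinal <- function(group) {
  bad <- setdiff(unique(group), analysis_groups())
  if (length(bad) > 0) {
    abort(sprintf("invalid analysis group: %s", paste(bad, collapse = ", ")))
  }
  ord <- setNames(1:7, analysis_groups()[1:7])
  unname(ord[group])
}
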