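# Builders for small in-code fixtures shared across the suite.

patient_row <- function(patient_id = "p1", syndrome = "fever_no_source",
                        syndrome_suggests = "neither", crp = NA_real_,
                        imaging_bacterial = NA, trivial = FALSE,
                        inflammatory = FALSE, other_infection = NA_character_,
                        pct = NA_real_, ngal = NA_real_, resistin = NA_real_) {
  tibble::tibble(
    patient_id = patient_id, syndrome = syndrome,
    syndrome_suggests = syndrome_suggests, crp_mg_per_l = crp,
    imaging_bacterial = imaging_bacterial, trivial_illness = trivial,
    inflammatory_suspected = inflammatory,
    distinct_other_infection = other_infection,
    pct_ug_per_l = pct, ngal_ng_per_ml = ngal, resistin_ng_per_ml = resistin
  )
}

finding_row <- function(patient_id = "p1", pathogen_name = "Escherichia coli",
                        pathogen_class = "bacterial", specimen_site = "urine",
                        method = "culture", clinically_consistent = TRUE) {
  tibble::tibble(
    patient_id = patient_id, pathogen_name = pathogen_name,
    pathogen_class = pathogen_class, specimen_site = specimen_site,
    method = method, clinically_consistent = clinically_consistent
  )
}

# independent pairwise-counting oracle for the AUC
auc_brute <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# random schema-valid patient records (paired with optional findings) for
# property-style tests over the rule engine
random_records <- function(n, seed) {
  set.seed(seed)
  syndromes <- c("pneumonia", "urinary_tract_infection", "sepsis",
                 "meningitis", "skin_soft_tissue", "bone_joint",
                 "upper_respiratory", "bronchiolitis", "gastroenteritis",
                 "fever_no_source", "other")
  patients <- tibble::tibble(
    patient_id = sprintf("r%03d", seq_len(n)),
    syndrome = sample(syndromes, n, replace = TRUE),
    syndrome_suggests = sample(c("bacterial", "viral", "neither", "either"),
                               n, replace = TRUE),
    crp_mg_per_l = ifelse(runif(n) < 0.15, NA_real_, rlnorm(n, log(30), 1.2)),
    imaging_bacterial = sample(c(TRUE, FALSE, NA), n, replace = TRUE),
    trivial_illness = runif(n) < 0.08,
    inflammatory_suspected = runif(n) < 0.08,
    distinct_other_infection = ifelse(runif(n) < 0.05, "tuberculosis",
                                      NA_character_)
  )
  has_finding <- runif(n) < 0.5
  findings <- tibble::tibble(
    patient_id = patients$patient_id[has_finding],
    pathogen_name = "organism",
    pathogen_class = sample(c("bacterial", "viral", "other"),
                            sum(has_finding), replace = TRUE),
    specimen_site = sample(c("blood", "urine", "CSF", "nasopharynx", "stool",
                             "skin"), sum(has_finding), replace = TRUE),
    method = sample(c("culture", "PCR", "antigen", "serology"),
                    sum(has_finding), replace = TRUE),
    clinically_consistent = runif(sum(has_finding)) < 0.6
  )
  list(patients = patients, findings = findings)
}
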