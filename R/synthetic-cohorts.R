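# Synthetic patient-level cohorts with the statistical structure the pipeline
# assumes: a configured mix of analysis groups, log-normal biomarker
# concentrations per group, CRP coupled to the biomarkers through a Gaussian
# copula on the log scale, and completely-at-random missingness. Each record
# carries clinical and microbiology fields constructed so the phenotype rule
# engine recovers the configured ground-truth group exactly.

#' Log-normal parameters from a printed median and IQR
#'
#' Fits `mu = log(median)` and `sigma = log(q3/q1) / (2 * qnorm(0.75))`. The
#' fit reproduces the median exactly and the IQR *ratio* exactly; a log-normal
#' cannot match two asymmetric quartiles independently, so the individual
#' quartiles are matched only through their ratio (a documented modelling
#' compromise).
#'
#' @param median,q1,q3 Printed median and quartiles, `0 < q1 <= median <= q3`,
#'   `q1 < q3`.
#' @return List with `mu` and `sigma` (log-scale mean and sd).
#' @export
#' @examples
#' lognormal_from_quartiles(2.40, 0.26, 10.95)
lognormal_from_quartiles <- function(median, q1, q3) {
  if (!(q1 > 0 && q1 <= median && median <= q3 && q1 < q3)) {
    abort("lognormal_from_quartiles: need 0 < q1 <= median <= q3 with q1 < q3")
  }
  list(mu = log(median), sigma = log(q3 / q1) / (2 * qnorm(0.75)))
}

#' Closed-form AUC between two log-normal groups
#'
#' With log-scale means `mu_pos > mu_neg` and sds `sigma_pos`, `sigma_neg`,
#' the probability a positive draw exceeds a negative draw is
#' `pnorm((mu_pos - mu_neg) / sqrt(sigma_pos^2 + sigma_neg^2))`.
#'
#' @param mu_pos,sigma_pos,mu_neg,sigma_neg Log-scale parameters.
#' @return The analytic AUC.
#' @export
lognormal_auc <- function(mu_pos, sigma_pos, mu_neg, sigma_neg) {
  pnorm((mu_pos - mu_neg) / sqrt(sigma_pos^2 + sigma_neg^2))
}

# clinical templates realizing each analysis group through fields the rule
# engine inspects; generator and classifier are mutually consistent by
# construction
fm_group_templates <- function() {
  t <- function(syndrome, suggests, crp_regime, trivial = FALSE,
                imaging = NA, finding = NULL) {
    list(syndrome = syndrome, syndrome_suggests = suggests,
         crp_regime = crp_regime, trivial_illness = trivial,
         imaging_bacterial = imaging, finding = finding)
  }
  fnd <- function(name, class, site, method, consistent) {
    tibble(pathogen_name = name, pathogen_class = class,
           specimen_site = site, method = method,
           clinically_consistent = consistent)
  }
  list(
    DEFINITE_BACTERIAL = t(
      "sepsis", "bacterial", "mixed",
      finding = fnd("Streptococcus pneumoniae", "bacterial", "blood",
                    "culture", TRUE)
    ),
    PROBABLE_BACTERIAL = t(
      "skin_soft_tissue", "bacterial", "above_cut",
      finding = fnd("Staphylococcus aureus", "bacterial", "skin",
                    "culture", TRUE)
    ),
    BACTERIAL_SYNDROME = t("pneumonia", "bacterial", "above_cut",
                           imaging = TRUE),
    UNKNOWN = t("fever_no_source", "neither", "mixed"),
    VIRAL_SYNDROME = t("upper_respiratory", "viral", "below_cut"),
    PROBABLE_VIRAL = t(
      "upper_respiratory", "viral", "below_cut",
      finding = fnd("Rhinovirus", "viral", "nasopharynx", "PCR", FALSE)
    ),
    DEFINITE_VIRAL = t(
      "bronchiolitis", "viral", "below_cut",
      finding = fnd("Respiratory syncytial virus", "viral", "nasopharynx",
                    "PCR", TRUE)
    ),
    OTHER = t("other", "neither", "mixed", trivial = TRUE)
  )
}

FM_DEFAULT_CRP <- tibble(
  group = analysis_groups(),
  crp_median = c(90, 110, 100, 25, 15, 15, 12, 8),
  crp_sdlog = c(1.0, 0.6, 0.6, 1.0, 1.0, 1.0, 1.0, 1.0)
)

#' Build a synthetic-cohort configuration
#'
#' @param cohort_id Cohort name.
#' @param categories Tibble with columns `group` (analysis group) and `n`;
#'   optional `crp_median`/`crp_sdlog` override the per-group CRP marginal
#'   (mg/L; log-normal). Groups requiring a raised (lowered) CRP for their
#'   phenotype are sampled from the marginal truncated above (below) the CRP
#'   cut, so the classifier round-trip is exact.
#' @param biomarkers Tibble with columns `group`, `biomarker` (`PCT`, `NGAL`,
#'   `resistin`), `median`, `q1`, `q3` giving the per-group log-normal fit
#'   targets. Biomarkers absent from this table are absent from the cohort.
#' @param crp_corr Named vector of target log-scale Pearson correlations
#'   between CRP and each biomarker (Gaussian copula).
#' @param marker_corr Exchangeable log-scale correlation between biomarkers.
#' @param missingness Named vector of per-biomarker missingness proportions
#'   in `[0, 1)`; applied completely at random with an exact count.
#' @param crp_cut CRP threshold the truncated sampling respects; keep equal to
#'   the classifier's `crp_cut_mg_per_l`.
#' @return List of class `fm_cohort_config`.
#' @export
cohort_config <- function(cohort_id, categories, biomarkers,
                          crp_corr = c(PCT = 0.33, NGAL = 0.31,
                                       resistin = 0.18),
                          marker_corr = 0.3,
                          missingness = c(PCT = 0, NGAL = 0, resistin = 0),
                          crp_cut = 60) {
  categories <- as_tibble(categories)
  biomarkers <- as_tibble(biomarkers)
  bad <- setdiff(unique(categories$group), analysis_groups())
  if (length(bad) > 0) {
    abort(sprintf("cohort_config: invalid group(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(categories$group)) abort("cohort_config: duplicate groups")
  if (any(categories$n < 0)) abort("cohort_config: n must be >= 0")
  if (!all(c("crp_median", "crp_sdlog") %in% names(categories))) {
    categories <- categories |>
      left_join(FM_DEFAULT_CRP, by = "group")
  }
  present <- intersect(names(FM_BIOMARKERS), unique(biomarkers$biomarker))
  bad <- setdiff(unique(biomarkers$biomarker), names(FM_BIOMARKERS))
  if (length(bad) > 0) {
    abort(sprintf("cohort_config: unknown biomarker(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (any(abs(crp_corr) >= 1) || abs(marker_corr) >= 1) {
    abort("cohort_config: correlations must lie in (-1, 1)")
  }
  miss <- missingness[present]
  miss[is.na(miss)] <- 0
  if (any(miss < 0 | miss >= 1)) {
    abort("cohort_config: missingness must lie in [0, 1)")
  }
  structure(
    list(
      cohort_id = cohort_id, categories = categories,
      biomarkers = biomarkers, present_biomarkers = present,
      crp_corr = crp_corr[present], marker_corr = marker_corr,
      missingness = setNames(as.numeric(miss), present),
      crp_cut = crp_cut
    ),
    class = "fm_cohort_config"
  )
}

#' @export
print.fm_cohort_config <- function(x, ...) {
  cat("<fm_cohort_config>", x$cohort_id, "\n")
  cat("  n =", sum(x$categories$n), "across",
      sum(x$categories$n > 0), "groups;",
      "biomarkers:", paste(x$present_biomarkers, collapse = ", "), "\n")
  invisible(x)
}

# deterministic substream seed below 2^31: Lehmer-style mix of the master
# seed with category and stream indices
fm_substream_seed <- function(master, category_index, stream) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  s <- (s * 48271 + category_index * 1103 + stream * 127) %% m
  as.integer(s)
}

# correlation matrix of the Gaussian copula: CRP first, then the biomarkers
fm_copula_chol <- function(config) {
  d <- length(config$present_biomarkers) + 1
  R <- matrix(config$marker_corr, d, d)
  R[1, -1] <- R[-1, 1] <- as.numeric(config$crp_corr)
  diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e) {
    abort("generate_cohort: correlation targets do not form a positive-definite matrix")
  })
  ch
}

#' Generate a synthetic cohort
#'
#' Draws the configured number of children per analysis group. For each group,
#' biomarkers are log-normal with the configured median/IQR-ratio fit, coupled
#' to each other and to CRP by a Gaussian copula; the CRP marginal is
#' truncated above or below the CRP cut where the group's phenotype demands
#' it (`mixed` groups are untruncated, so their log-scale correlations match
#' the copula targets exactly). Clinical and microbiology fields follow fixed
#' per-group templates so that [classify_cohort()] recovers `true_group` for
#' every record. Missingness is applied per biomarker completely at random
#' with an exact count `round(p * n)`. The draw is fully reproducible: the
#' single seed expands into independent substreams per group and biomarker
#' stream, so adding a group does not perturb the others.
#'
#' @param config [cohort_config()] object.
#' @param seed Integer master seed.
#' @return `fm_cohort` whose `patients` tibble carries a `true_group` column.
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "fm_cohort_config"))
  templates <- fm_group_templates()
  ch <- fm_copula_chol(config)
  markers <- config$present_biomarkers
  cats <- config$categories |> filter(.data$n > 0)

  blocks <- map(seq_len(nrow(cats)), function(i) {
    row <- cats[i, ]
    tpl <- templates[[row$group]]
    gi <- match(row$group, analysis_groups())
    n <- row$n
    set.seed(fm_substream_seed(seed, gi, 1L))
    Z <- matrix(rnorm(n * (length(markers) + 1)), nrow = n) %*% ch
    U <- pnorm(Z)

    # CRP: truncate the uniform into the region the phenotype requires
    crp_par <- list(mu = log(row$crp_median), sigma = row$crp_sdlog)
    f_cut <- stats::plnorm(config$crp_cut, crp_par$mu, crp_par$sigma)
    u_crp <- switch(tpl$crp_regime,
      above_cut = f_cut + U[, 1] * (1 - f_cut),
      below_cut = U[, 1] * f_cut,
      mixed = U[, 1],
      abort(sprintf("unknown crp_regime '%s'", tpl$crp_regime))
    )
    crp <- qlnorm(pmin(u_crp, 1 - 1e-12), crp_par$mu, crp_par$sigma)

    vals <- map(seq_along(markers), function(j) {
      par_row <- config$biomarkers |>
        filter(.data$group == row$group, .data$biomarker == markers[j])
      if (nrow(par_row) == 0) {
        return(rep(NA_real_, n))
      }
      par <- lognormal_from_quartiles(par_row$median[1], par_row$q1[1],
                                      par_row$q3[1])
      qlnorm(U[, j + 1], par$mu, par$sigma)
    })
    names(vals) <- unname(FM_BIOMARKERS[markers])

    ids <- sprintf("%s_%s_%04d", config$cohort_id, gi, seq_len(n))
    patients <- tibble(
      patient_id = ids,
      cohort_id = config$cohort_id,
      age_months = NA_real_,
      syndrome = tpl$syndrome,
      syndrome_suggests = tpl$syndrome_suggests,
      imaging_bacterial = tpl$imaging_bacterial,
      crp_mg_per_l = crp,
      pct_ug_per_l = NA_real_, ngal_ng_per_ml = NA_real_,
      resistin_ng_per_ml = NA_real_,
      inflammatory_suspected = FALSE,
      trivial_illness = tpl$trivial_illness,
      distinct_other_infection = NA_character_,
      true_group = row$group
    )
    for (col in names(vals)) patients[[col]] <- vals[[col]]
    findings <- if (!is.null(tpl$finding)) {
      tidyr::crossing(tibble(patient_id = ids), tpl$finding)
    } else {
      NULL
    }
    list(patients = patients, findings = findings)
  })

  if (length(blocks) == 0) {
    patients <- validate_patients(tibble(
      patient_id = character(), syndrome = character(),
      syndrome_suggests = character()
    ))
    patients$true_group <- character()
    return(new_cohort(patients, validate_findings(NULL, patients),
                      cohort_id = config$cohort_id,
                      provenance = sprintf("generate_cohort(seed = %d)", seed)))
  }
  patients <- list_rbind(map(blocks, "patients"))
  findings <- purrr::compact(map(blocks, "findings"))
  findings <- if (length(findings) > 0) list_rbind(findings) else NULL
  if (nrow(patients) > 0) {
    # completely-at-random missingness, exact per-biomarker count
    for (j in seq_along(markers)) {
      p <- config$missingness[[markers[j]]]
      if (p > 0) {
        set.seed(fm_substream_seed(seed, 97L + j, 2L))
        k <- round(p * nrow(patients))
        drop <- sample.int(nrow(patients), k)
        patients[[FM_BIOMARKERS[[markers[j]]]]][drop] <- NA_real_
      }
    }
  }
  if (is.null(findings)) {
    findings <- validate_findings(NULL, patients)
  }
  new_cohort(
    patients, findings, cohort_id = config$cohort_id,
    provenance = sprintf("generate_cohort(seed = %d)", seed)
  )
}

# ---------------------------------------------------------------------------
# Presets emulating the five published cohorts: analysis-population category
# counts and per-group biomarker median/IQR targets transcribed from the
# printed per-cohort concentration table; per-biomarker missingness set so the
# expected complete-case counts match the printed per-biomarker N.
# Cells printed without a median/IQR fall back to the cohort's overall column.

fm_preset_table <- function() {
  g <- analysis_groups()
  mk <- function(ns, pct = NULL, ngal = NULL, resistin = NULL) {
    bm <- list(PCT = pct, NGAL = ngal, resistin = resistin)
    rows <- imap(bm, function(m, name) {
      if (is.null(m)) return(NULL)
      tibble(group = g, biomarker = name,
             median = m[, 1], q1 = m[, 2], q3 = m[, 3])
    })
    list(categories = tibble(group = g, n = ns),
         biomarkers = list_rbind(purrr::compact(rows)))
  }
  # row order: DB, PB, BS, UNKNOWN, VS, PV, DV, OTHER
  list(
    alderhey_ed = c(
      mk(
        ns = c(78, 169, 107, 33, 46, 559, 88, 81),
        pct = rbind(
          c(2.40, 0.26, 10.95), c(1.08, 0.28, 3.00), c(0.16, 0.09, 0.52),
          c(0.20, 0.10, 0.52), c(0.65, 0.33, 1.40), c(0.15, 0.08, 0.38),
          c(0.21, 0.13, 0.54), c(0.23, 0.10, 0.80)
        ),
        ngal = rbind(
          c(140.0, 82.1, 228.8), c(105.9, 80.7, 160.0), c(83.6, 57.9, 123.4),
          c(77.2, 63.1, 101.8), c(99.0, 68.1, 148.8), c(63.4, 43.8, 93.8),
          c(75.4, 53.3, 101.9), c(78.1, 52.5, 121.1)
        ),
        resistin = rbind(
          c(67.8, 34.8, 124.1), c(59.8, 33.6, 105.0), c(45.1, 28.1, 87.7),
          c(27.0, 16.7, 52.9), c(40.6, 18.8, 73.7), c(33.9, 18.6, 61.9),
          c(35.6, 17.6, 63.0), c(40.3, 21.5, 73.7)
        )
      ),
      list(missing_n = c(PCT = 54, NGAL = 41, resistin = 42), total = 1161)
    ),
    alderhey_picu = c(
      mk(
        ns = c(48, 73, 79, 92, 5, 1, 48, 6),
        pct = rbind(
          c(12.95, 1.07, 98.0), c(1.00, 0.18, 8.30), c(0.28, 0.08, 2.41),
          c(0.43, 0.09, 2.55), c(8.2, 8.1, 23.3), c(0.64, 0.10, 5.58),
          c(0.38, 0.11, 0.83), c(0.64, 0.10, 5.58)
        ),
        ngal = rbind(
          c(170.1, 91.7, 291.5), c(126.1, 97.2, 229.1), c(102.8, 71.8, 189.9),
          c(125.3, 71.2, 227.1), c(93.2, 42.7, 157.0), c(116.0, 70.5, 198.5),
          c(72.1, 51.3, 116.7), c(116.0, 70.5, 198.5)
        ),
        resistin = rbind(
          c(57.1, 26.1, 169.3), c(73.8, 48.5, 155.4), c(45.6, 31.1, 87.4),
          c(46.3, 31.6, 73.6), c(80.7, 50.5, 110.2), c(54.4, 29.1, 97.8),
          c(37.3, 13.4, 67.1), c(54.4, 29.1, 97.8)
        )
      ),
      list(missing_n = c(PCT = 6, NGAL = 170, resistin = 168), total = 352)
    ),
    erasmus_ed = c(
      mk(
        ns = c(34, 52, 61, 25, 43, 442, 53, 0),
        pct = rbind(
          c(0.64, 0.24, 3.02), c(1.49, 0.54, 6.19), c(0.23, 0.11, 0.67),
          c(0.14, 0.08, 0.24), c(0.52, 0.21, 1.92), c(0.14, 0.09, 0.29),
          c(0.15, 0.09, 0.35), c(0.18, 0.10, 0.54)
        )
      ),
      list(missing_n = c(PCT = 0), total = 710)
    ),
    maasstad_ed = c(
      mk(
        ns = c(30, 30, 35, 14, 28, 215, 34, 0),
        pct = rbind(
          c(1.36, 0.33, 2.38), c(1.76, 0.35, 4.96), c(0.17, 0.07, 0.42),
          c(0.10, 0.05, 0.30), c(0.43, 0.21, 1.53), c(0.16, 0.09, 0.35),
          c(0.18, 0.10, 0.60), c(0.21, 0.10, 0.67)
        )
      ),
      list(missing_n = c(PCT = 0), total = 386)
    ),
    st_marys = c(
      mk(
        ns = c(38, 38, 0, 32, 0, 0, 43, 49),
        ngal = rbind(
          c(285.2, 235.3, 639.8), c(187.3, 118.4, 308.3),
          c(132.1, 76.6, 248.9), c(144.0, 89.7, 209.3),
          c(132.1, 76.6, 248.9), c(132.1, 76.6, 248.9),
          c(97.9, 62.7, 161.2), c(132.1, 76.6, 248.9)
        )
      ),
      list(missing_n = c(NGAL = 0), total = 200)
    )
  )
}

#' Preset synthetic-cohort configurations
#'
#' `preset_names()` lists the five available presets;
#' `preset_cohort_config()` returns one as a ready [cohort_config()]. The
#' presets emulate the five published pediatric cohorts: category counts and
#' per-group biomarker medians/IQRs follow the printed per-cohort
#' concentration table (PCT/NGAL/resistin for the Alder Hey cohorts, PCT only
#' for Erasmus and Maasstad, NGAL only for St. Mary's), with per-biomarker
#' missingness matching the printed analysis N's.
#'
#' @param name One of `preset_names()`.
#' @return An `fm_cohort_config`.
#' @export
#' @examples
#' preset_cohort_config("erasmus_ed")
preset_cohort_config <- function(name) {
  tab <- fm_preset_table()
  if (!name %in% names(tab)) {
    abort(sprintf("unknown preset '%s'; available: %s",
                  name, paste(names(tab), collapse = ", ")))
  }
  p <- tab[[name]]
  present <- unique(p$biomarkers$biomarker)
  cohort_config(
    cohort_id = name,
    categories = p$categories,
    biomarkers = p$biomarkers,
    missingness = p$missing_n / p$total
  )
}

#' @rdname preset_cohort_config
#' @export
preset_names <- function() names(fm_preset_table())

#' Demonstration configuration with a monotone bacterial-to-viral gradient
#'
#' A single-biomarker (PCT) configuration whose per-group medians decrease
#' strictly from definite bacterial to definite viral, for exercising the
#' spectrum correlation: concentrations sampled from it correlate negatively
#' with the spectrum ordinal.
#'
#' @param n_per_group Children per infection group (7 groups).
#' @return An `fm_cohort_config`.
#' @export
monotone_gradient_config <- function(n_per_group = 143) {
  g <- analysis_groups()[1:7]
  med <- c(2.40, 1.10, 0.60, 0.35, 0.25, 0.18, 0.15)
  cohort_config(
    cohort_id = "gradient_demo",
    categories = tibble(group = g, n = n_per_group),
    biomarkers = tibble(
      group = g, biomarker = "PCT",
      median = med, q1 = med / 2.5, q3 = med * 2.5
    )
  )
}

#' Read and write a cohort configuration as YAML
#'
#' Round-trips an [cohort_config()] through a plain-text YAML file.
#'
#' @param config An `fm_cohort_config`.
#' @param path File path.
#' @return `read_cohort_config()` returns an `fm_cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "fm_cohort_config"))
  yaml::write_yaml(
    list(
      cohort_id = config$cohort_id,
      categories = lapply(seq_len(nrow(config$categories)), function(i) {
        as.list(config$categories[i, ])
      }),
      biomarkers = lapply(seq_len(nrow(config$biomarkers)), function(i) {
        as.list(config$biomarkers[i, ])
      }),
      crp_corr = as.list(config$crp_corr),
      marker_corr = config$marker_corr,
      missingness = as.list(config$missingness),
      crp_cut = config$crp_cut
    ),
    path,
    precision = 15
  )
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cohort_config(
    cohort_id = cfg$cohort_id,
    categories = list_rbind(map(cfg$categories, as_tibble)),
    biomarkers = list_rbind(map(cfg$biomarkers, as_tibble)),
    crp_corr = unlist(cfg$crp_corr),
    marker_corr = cfg$marker_corr,
    missingness = unlist(cfg$missingness),
    crp_cut = cfg$crp_cut
  )
}
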