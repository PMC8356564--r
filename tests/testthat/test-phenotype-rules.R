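test_that("definite bacterial requires sterile-site isolation and dominates other evidence", {
  pts <- patient_row("a", syndrome = "sepsis", syndrome_suggests = "bacterial",
                     crp = 180)
  fnd <- finding_row("a", "Streptococcus pneumoniae", "bacterial", "blood",
                     "culture", TRUE)
  expect_equal(classify_perform(pts, fnd), "DEFINITE_BACTERIAL")

  # co-detected virus does not displace sterile-site bacterial evidence
  fnd2 <- dplyr::bind_rows(
    fnd,
    finding_row("a", "RSV", "viral", "nasopharynx", "PCR", TRUE)
  )
  pts2 <- patient_row("a", syndrome = "bronchiolitis",
                      syndrome_suggests = "viral", crp = 10)
  expect_equal(classify_perform(pts2, fnd2), "DEFINITE_BACTERIAL")
})

test_that("viral branch resolves by virus detection, consistency and CRP", {
  rsv <- finding_row("b", "RSV", "viral", "nasopharynx", "PCR", TRUE)
  below <- patient_row("b", syndrome = "bronchiolitis",
                       syndrome_suggests = "viral", crp = 12)
  expect_equal(classify_perform(below, rsv), "DEFINITE_VIRAL")

  # virus found but not adjudicated consistent: probable viral
  rhino <- finding_row("b", "Rhinovirus", "viral", "nasopharynx", "PCR", FALSE)
  expect_equal(classify_perform(below, rhino), "PROBABLE_VIRAL")

  # viral phenotype, no virus, low CRP: viral syndrome
  expect_equal(classify_perform(below, NULL), "VIRAL_SYNDROME")

  # viral phenotype with unexplained raised CRP: viral syndrome if a virus
  # was found, unknown otherwise
  above <- patient_row("b", syndrome = "bronchiolitis",
                       syndrome_suggests = "viral", crp = 150)
  expect_equal(classify_perform(above, rsv), "VIRAL_SYNDROME")
  expect_equal(classify_perform(above, NULL), "UNKNOWN")
})

test_that("bacterial branch below the sterile node follows isolate, phenotype and CRP", {
  skin <- finding_row("c", "Staphylococcus aureus", "bacterial", "skin",
                      "culture", TRUE)
  high <- patient_row("c", syndrome = "skin_soft_tissue",
                      syndrome_suggests = "bacterial", crp = 120)
  expect_equal(classify_perform(high, skin), "PROBABLE_BACTERIAL")

  # bacterial phenotype without isolate and raised CRP: bacterial syndrome
  expect_equal(classify_perform(high, NULL), "BACTERIAL_SYNDROME")

  # same phenotype with low CRP: unknown
  low <- patient_row("c", syndrome = "skin_soft_tissue",
                     syndrome_suggests = "bacterial", crp = 10)
  expect_equal(classify_perform(low, skin), "UNKNOWN")
  expect_equal(classify_perform(low, NULL), "UNKNOWN")
})

test_that("non-infection categories classify from their flags", {
  expect_equal(classify_perform(patient_row("d", trivial = TRUE)), "TRIVIAL")
  expect_equal(
    classify_perform(patient_row("d", other_infection = "malaria")),
    "OTHER_INFECTION"
  )
  expect_equal(
    classify_perform(patient_row("d", inflammatory = TRUE)),
    "INFLAMMATORY_SYNDROME"
  )
  expect_equal(
    classify_perform(
      patient_row("d", inflammatory = TRUE, syndrome_suggests = "viral",
                  crp = 20)
    ),
    "INFECTION_OR_INFLAMMATION"
  )
  expect_equal(
    classify_perform(patient_row("d", syndrome = "fever_no_source",
                                 syndrome_suggests = "neither", crp = 20)),
    "UNKNOWN"
  )
})

test_that("missing CRP at a CRP node yields UNKNOWN with an audit flag, never an error", {
  pts <- patient_row("e", syndrome = "pneumonia",
                     syndrome_suggests = "bacterial", crp = NA_real_)
  out <- classify_cohort(pts)
  expect_equal(out$perform_category, "UNKNOWN")
  expect_equal(out$audit_flag, "missing-CRP")
  expect_match(out$audit_path, "crp_bacterial_phenotype=missing")

  # records that never reach a CRP node carry no flag
  out2 <- classify_cohort(patient_row("e", trivial = TRUE))
  expect_true(is.na(out2$audit_flag))
})

test_that("SBI reference standard covers its four evidence routes", {
  # sterile-site isolation (urine counts as sterile)
  expect_equal(
    classify_sbi(
      patient_row("f", syndrome = "urinary_tract_infection",
                  syndrome_suggests = "bacterial"),
      finding_row("f", "Escherichia coli", "bacterial", "urine", "culture",
                  TRUE)
    ),
    "SBI"
  )
  # imaging with compatible syndrome
  expect_equal(
    classify_sbi(patient_row("f", syndrome = "pneumonia",
                             syndrome_suggests = "either",
                             imaging_bacterial = TRUE)),
    "SBI"
  )
  # consistent non-sterile isolate with compatible syndrome
  expect_equal(
    classify_sbi(
      patient_row("f", syndrome = "skin_soft_tissue",
                  syndrome_suggests = "bacterial"),
      finding_row("f", "Staphylococcus aureus", "bacterial", "skin",
                  "culture", TRUE)
    ),
    "SBI"
  )
  # clinical bacterial diagnosis without microbiology
  expect_equal(
    classify_sbi(patient_row("f", syndrome = "sepsis",
                             syndrome_suggests = "bacterial")),
    "SBI"
  )
  # viral bronchiolitis is not an SBI
  expect_equal(
    classify_sbi(
      patient_row("f", syndrome = "bronchiolitis",
                  syndrome_suggests = "viral", imaging_bacterial = FALSE),
      finding_row("f", "RSV", "viral", "nasopharynx", "PCR", TRUE)
    ),
    "NON_SBI"
  )
})

test_that("collapse maps exactly the four non-infection categories to OTHER", {
  expect_equal(collapse_other("TRIVIAL"), "OTHER")
  expect_equal(collapse_other("INFLAMMATORY_SYNDROME"), "OTHER")
  expect_equal(collapse_other("OTHER_INFECTION"), "OTHER")
  expect_equal(collapse_other("INFECTION_OR_INFLAMMATION"), "OTHER")
  infection <- analysis_groups()[1:7]
  expect_equal(collapse_other(infection), infection)
  expect_error(collapse_other("NOT_A_CATEGORY"), "invalid")
  expect_length(perform_categories(), 11)
  expect_length(analysis_groups(), 8)
})

test_that("spectrum ordinal is a strict order embedding of the seven infection groups", {
  expect_equal(spectrum_ordinal("DEFINITE_BACTERIAL"), 1L)
  expect_equal(spectrum_ordinal("DEFINITE_VIRAL"), 7L)
  expect_true(is.na(spectrum_ordinal("OTHER")))
  ords <- spectrum_ordinal(analysis_groups()[1:7])
  expect_equal(ords, 1:7)
  expect_error(spectrum_ordinal("TRIVIAL"), "invalid")
})

test_that("every schema-valid record maps to exactly one category, deterministically", {
  rec <- random_records(300, seed = 42)
  out1 <- classify_cohort(rec$patients, rec$findings)
  out2 <- classify_cohort(rec$patients, rec$findings)
  expect_identical(out1, out2)
  expect_true(all(out1$perform_category %in% perform_categories()))
  expect_true(all(out1$analysis_group %in% analysis_groups()))
  expect_true(all(out1$sbi_label %in% c("SBI", "NON_SBI")))
  expect_false(anyNA(out1$perform_category))
  # collapse is consistent with the audit category
  expect_equal(out1$analysis_group, collapse_other(out1$perform_category))
})

test_that("raising CRP across the cut never moves a label toward the viral end", {
  crp_grid <- c(1, 30, 59.99, 60, 61, 120, 400)
  scenarios <- list(
    list(p = patient_row("m", syndrome = "pneumonia",
                         syndrome_suggests = "bacterial"), f = NULL),
    list(p = patient_row("m", syndrome = "skin_soft_tissue",
                         syndrome_suggests = "bacterial"),
         f = finding_row("m", "Staphylococcus aureus", "bacterial", "skin",
                         "culture", TRUE)),
    list(p = patient_row("m", syndrome = "bronchiolitis",
                         syndrome_suggests = "viral"),
         f = finding_row("m", "RSV", "viral", "nasopharynx", "PCR", TRUE)),
    list(p = patient_row("m", syndrome = "bronchiolitis",
                         syndrome_suggests = "viral"), f = NULL)
  )
  # ordinal scale extended so OTHER/non-spectrum never appears here
  for (sc in scenarios) {
    ords <- vapply(crp_grid, function(crp) {
      sc$p$crp_mg_per_l <- crp
      g <- collapse_other(classify_perform(sc$p, sc$f))
      spectrum_ordinal(g)
    }, integer(1))
    expect_true(all(diff(ords) <= 0),
                info = paste("ordinal increased with CRP:",
                             paste(ords, collapse = ",")))
  }
})

test_that("schema violations are rejected with the offending field named", {
  expect_error(
    classify_cohort(dplyr::bind_rows(patient_row("x"), patient_row("x"))),
    "duplicate patient_id"
  )
  bad <- patient_row("x"); bad$syndrome <- "common_cold"
  expect_error(classify_cohort(bad), "syndrome")
  neg <- patient_row("x", crp = -5)
  expect_error(classify_cohort(neg), "crp_mg_per_l")
  expect_error(
    classify_cohort(patient_row("x"),
                    finding_row("y", specimen_site = "blood")),
    "y"
  )
  # declared sterility must agree with the configured sterile-site list
  f <- finding_row("x", specimen_site = "nasopharynx")
  f$site_sterile <- TRUE
  expect_error(classify_cohort(patient_row("x"), f), "sterile")
})
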