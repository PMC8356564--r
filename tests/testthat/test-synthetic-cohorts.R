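test_that("log-normal fit reproduces the median and IQR ratio exactly", {
  fit <- lognormal_from_quartiles(2.40, 0.26, 10.95)
  expect_equal(fit$mu, log(2.40))
  expect_equal(round(fit$mu, 4), 0.8755)
  expect_equal(round(fit$sigma, 3), 2.773)
  # fitted quartile ratio equals the printed ratio
  z75 <- qnorm(0.75)
  expect_equal(exp(2 * z75 * fit$sigma), 10.95 / 0.26, tolerance = 1e-12)
  # standard log-normal quartiles recover mu = 0, sigma = 1
  std <- lognormal_from_quartiles(1, exp(-z75), exp(z75))
  expect_equal(std$mu, 0)
  expect_equal(std$sigma, 1)
  expect_error(lognormal_from_quartiles(1, 1, 1), "q1 < q3")
  expect_error(lognormal_from_quartiles(1, 2, 3), "q1 <= median")
})

test_that("generation is deterministic and groups survive classification unchanged", {
  cfg <- monotone_gradient_config(n_per_group = 30)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a$patients, b$patients)
  expect_identical(a$findings, b$findings)
  c2 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(a$patients$pct_ug_per_l, c2$patients$pct_ug_per_l))

  cls <- classify_cohort(a$patients, a$findings)
  expect_equal(cls$analysis_group, a$patients$true_group)

  # adding a group does not perturb existing substreams
  cfg_plus <- cohort_config(
    cohort_id = cfg$cohort_id,
    categories = dplyr::bind_rows(cfg$categories,
                                  tibble::tibble(group = "OTHER", n = 10)),
    biomarkers = cfg$biomarkers
  )
  d <- generate_cohort(cfg_plus, seed = 5)
  keep <- d$patients$true_group != "OTHER"
  expect_equal(d$patients$pct_ug_per_l[keep], a$patients$pct_ug_per_l)
})

test_that("an all-zero configuration yields an empty cohort", {
  cfg <- cohort_config(
    "empty",
    categories = tibble::tibble(group = analysis_groups(), n = 0),
    biomarkers = tibble::tibble(group = "UNKNOWN", biomarker = "PCT",
                                median = 1, q1 = 0.5, q3 = 2)
  )
  co <- generate_cohort(cfg, seed = 1)
  expect_equal(nrow(co$patients), 0)
  expect_equal(nrow(co$findings), 0)
})

test_that("presets transcribe the five cohorts' structure", {
  expect_setequal(
    preset_names(),
    c("alderhey_ed", "alderhey_picu", "erasmus_ed", "maasstad_ed", "st_marys")
  )
  # the Erasmus cohort is PCT-only with 710 PCT-bearing children
  er <- preset_cohort_config("erasmus_ed")
  expect_equal(er$present_biomarkers, "PCT")
  co <- generate_cohort(er, seed = 2)
  expect_equal(nrow(complete_cases(co$patients, "PCT")), 710)

  # PICU definite-viral PCT cell: median 0.38, IQR 0.11-0.83, n = 48
  picu <- preset_cohort_config("alderhey_picu")
  dv <- dplyr::filter(picu$biomarkers, group == "DEFINITE_VIRAL",
                      biomarker == "PCT")
  expect_equal(c(dv$median, dv$q1, dv$q3), c(0.38, 0.11, 0.83))
  expect_equal(
    dplyr::filter(picu$categories, group == "DEFINITE_VIRAL")$n, 48
  )

  # St Mary's carries NGAL only; asking for PCT is an error downstream
  sm <- generate_cohort(preset_cohort_config("st_marys"), seed = 2)
  expect_equal(nrow(sm$patients), 200)
  expect_error(complete_cases(sm$patients |> dplyr::select(-pct_ug_per_l),
                              "PCT"), "absent")
  expect_true(all(is.na(sm$patients$pct_ug_per_l)))
  expect_error(preset_cohort_config("nonexistent"), "alderhey_ed")
})

test_that("missingness removes an exact per-biomarker count at random", {
  ah <- preset_cohort_config("alderhey_ed")
  co <- generate_cohort(ah, seed = 3)
  expect_equal(nrow(co$patients), 1161)
  expect_equal(sum(is.na(co$patients$pct_ug_per_l)), 54)
  expect_equal(sum(is.na(co$patients$ngal_ng_per_ml)), 41)
  expect_equal(sum(is.na(co$patients$resistin_ng_per_ml)), 42)
  expect_equal(nrow(complete_cases(co$patients, "PCT")), 1107)
})

test_that("truncated CRP sampling honours the phenotype's side of the cut", {
  ah <- generate_cohort(preset_cohort_config("alderhey_ed"), seed = 4)
  p <- ah$patients
  above <- p$true_group %in% c("PROBABLE_BACTERIAL", "BACTERIAL_SYNDROME")
  below <- p$true_group %in% c("VIRAL_SYNDROME", "PROBABLE_VIRAL",
                               "DEFINITE_VIRAL")
  expect_true(all(p$crp_mg_per_l[above] >= 60))
  expect_true(all(p$crp_mg_per_l[below] < 60))
})

test_that("closed-form two-group AUC matches the generator at moderate n", {
  g <- c("DEFINITE_BACTERIAL", "DEFINITE_VIRAL")
  z75 <- qnorm(0.75)
  # medians 4 and 1 with common sigma from IQR ratio 9
  sigma <- log(9) / (2 * z75)
  cfg <- cohort_config(
    "auc_demo",
    categories = tibble::tibble(group = g, n = 4000),
    biomarkers = tibble::tibble(
      group = g, biomarker = "PCT",
      median = c(4, 1), q1 = c(4, 1) / 3, q3 = c(4, 1) * 3
    )
  )
  co <- generate_cohort(cfg, seed = 8)
  pos <- co$patients$pct_ug_per_l[co$patients$true_group == g[1]]
  neg <- co$patients$pct_ug_per_l[co$patients$true_group == g[2]]
  expected <- lognormal_auc(log(4), sigma, log(1), sigma)
  expect_equal(expected, pnorm(log(4) / (sigma * sqrt(2))))
  got <- roc_auc(c(pos, neg), rep(c("p", "n"), each = 4000),
                 positive = "p")$auc
  expect_lt(abs(got - expected), 0.015)
})

test_that("cohort configuration round-trips through YAML", {
  dir <- withr::local_tempdir()
  cfg <- preset_cohort_config("alderhey_picu")
  write_cohort_config(cfg, file.path(dir, "cfg.yaml"))
  back <- read_cohort_config(file.path(dir, "cfg.yaml"))
  expect_equal(back$cohort_id, cfg$cohort_id)
  expect_equal(as.data.frame(back$categories), as.data.frame(cfg$categories))
  expect_equal(as.data.frame(back$biomarkers), as.data.frame(cfg$biomarkers))
  expect_equal(back$crp_corr, cfg$crp_corr)
  expect_equal(back$missingness, cfg$missingness)
  expect_identical(generate_cohort(back, seed = 9)$patients,
                   generate_cohort(cfg, seed = 9)$patients)
})

test_that("invalid configurations are rejected", {
  expect_error(
    cohort_config("x", tibble::tibble(group = "NOT_A_GROUP", n = 5),
                  tibble::tibble(group = "UNKNOWN", biomarker = "PCT",
                                 median = 1, q1 = 0.5, q3 = 2)),
    "invalid group"
  )
  expect_error(
    cohort_config("x", tibble::tibble(group = "UNKNOWN", n = 5),
                  tibble::tibble(group = "UNKNOWN", biomarker = "CD64",
                                 median = 1, q1 = 0.5, q3 = 2)),
    "unknown biomarker"
  )
  expect_error(
    cohort_config("x", tibble::tibble(group = "UNKNOWN", n = 5),
                  tibble::tibble(group = "UNKNOWN", biomarker = "PCT",
                                 median = 1, q1 = 0.5, q3 = 2),
                  marker_corr = 1.2),
    "correlations"
  )
})
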