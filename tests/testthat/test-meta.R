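test_that("standard errors recovered from printed intervals use the exact normal quantile", {
  expect_equal(se_from_ci(0.77, 0.72, 0.82), 0.1 / (2 * qnorm(0.975)))
  expect_equal(round(se_from_ci(0.77, 0.72, 0.82), 6), 0.025511)
  expect_equal(round(se_from_ci(0.5, 0.4, 0.6), 6), 0.051021)
  expect_error(se_from_ci(0.5, 0.5, 0.5), "zero-width")
  expect_error(se_from_ci(0.5, 0.6, 0.7), "bracket")
  expect_error(se_from_ci(0.5, 0.4, 0.6, level = 1.2), "level")
})

test_that("Cochran's Q matches hand computation and is shift-invariant", {
  expect_equal(cochran_q(c(0.7, 0.7), c(0.1, 0.1))$q, 0)
  qq <- cochran_q(c(0.6, 0.8), c(0.1, 0.1))
  expect_equal(qq$q, 2.0)
  expect_equal(qq$df, 1L)
  set.seed(13)
  y <- runif(6); s <- runif(6, 0.05, 0.2)
  expect_equal(cochran_q(y, s)$q, cochran_q(y + 10, s)$q, tolerance = 1e-10)
  expect_warning(cochran_q(0.5, 0.1), "fewer than 2")
})

test_that("between-study variance estimators behave per their definitions", {
  # DL hand computation: Q = 2, df = 1, C = 100 -> tau2 = 0.01
  expect_equal(tau2_estimate(c(0.6, 0.8), c(0.1, 0.1), method = "DL"), 0.01)
  # floor at zero when under-dispersed; DL and REML then agree exactly
  y <- c(0.70, 0.71); s <- c(0.1, 0.1)
  expect_equal(tau2_estimate(y, s, "DL"), 0)
  expect_equal(tau2_estimate(y, s, "REML"), 0)
  expect_equal(tau2_estimate(c(0.7, 0.7), c(0.1, 0.1), "REML"), 0)

  skip_if_not_installed("metafor")
  set.seed(17)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    y <- runif(k, 0.5, 0.9)
    s <- runif(k, 0.02, 0.12)
    expect_equal(
      tau2_estimate(y, s, "DL"),
      unname(metafor::rma(yi = y, sei = s, method = "DL")$tau2),
      tolerance = 1e-8
    )
    ref <- unname(metafor::rma(yi = y, sei = s, method = "REML",
                               control = list(threshold = 1e-12,
                                              maxiter = 10000))$tau2)
    expect_lt(abs(tau2_estimate(y, s, "REML") - ref), 1e-7)
  }
})

test_that("random-effects pooling matches the hand-computed two-study case", {
  st <- tibble::tibble(label = c("A", "B"), auc = c(0.6, 0.8),
                       se = c(0.1, 0.1))
  m <- pool_random_effects(st, effect = "auc", se = "se", label = "label",
                           method = "DL")
  expect_equal(m$pooled, 0.70)
  expect_equal(m$q, 2.0)
  expect_equal(m$tau2, 0.01)
  expect_equal(m$i2_percent, 50)
  expect_equal(c(m$ci_low, m$ci_high), c(0.504, 0.896), tolerance = 5e-4)
  expect_equal(m$p_heterogeneity, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(round(m$p_heterogeneity, 4), 0.1573)

  # two identical studies: diamond coincides with the squares
  same <- tibble::tibble(auc = c(0.75, 0.75), se = c(0.05, 0.05))
  m2 <- pool_random_effects(same, "auc", "se")
  expect_equal(m2$pooled, 0.75)
  expect_equal(m2$q, 0)
  expect_equal(m2$i2_percent, 0)
})

test_that("pooled estimate respects its structural invariants", {
  set.seed(19)
  for (i in 1:20) {
    k <- sample(2:7, 1)
    st <- tibble::tibble(auc = runif(k, 0.4, 0.95),
                         se = runif(k, 0.02, 0.15))
    for (method in c("DL", "REML")) {
      m <- pool_random_effects(st, "auc", "se", method = method)
      expect_gte(m$pooled, min(st$auc))
      expect_lte(m$pooled, max(st$auc))
      expect_true(m$ci_low <= m$pooled && m$pooled <= m$ci_high)
      expect_gte(m$tau2, 0)
      expect_gte(m$i2_percent, 0)
      expect_lt(m$i2_percent, 100)
      if (m$q <= m$df) expect_equal(m$i2_q_percent, 0)
      if (m$tau2 == 0) {
        # at tau2 = 0 the pooled value equals the fixed-effect mean
        w <- 1 / st$se^2
        expect_equal(m$pooled, sum(w * st$auc) / sum(w), tolerance = 1e-12)
      }
    }
  }
})

test_that("pooling agrees with the reference meta-analysis implementation", {
  skip_if_not_installed("metafor")
  tab <- read_auc_table(table4_auc_path())
  rows <- dplyr::filter(tab, biomarker == "PCT", contrast == "DB_vs_DV")
  rows$se <- se_from_ci(rows$auc, rows$ci_low, rows$ci_high)
  for (method in c("DL", "REML")) {
    m <- pool_random_effects(rows, "auc", "se", label = "study",
                             method = method)
    ref <- metafor::rma(yi = rows$auc, sei = rows$se, method = method)
    expect_equal(m$pooled, as.numeric(ref$b), tolerance = 1e-6)
    expect_equal(m$ci_low, ref$ci.lb, tolerance = 1e-5)
    expect_equal(m$ci_high, ref$ci.ub, tolerance = 1e-5)
    expect_equal(m$q, ref$QE, tolerance = 1e-8)
    expect_equal(m$i2_percent, ref$I2, tolerance = 1e-4)
  }
})

test_that("the two printed resistin DB-vs-DV studies are homogeneous", {
  st <- tibble::tibble(
    auc = c(0.70, 0.65),
    se = se_from_ci(c(0.70, 0.65), c(0.61, 0.50), c(0.78, 0.79))
  )
  m <- pool_random_effects(st, "auc", "se")
  expect_lt(m$q, 1)
  expect_equal(m$i2_percent, 0)
})

test_that("forest data carries squares, diamond and caption in plot order", {
  st <- tibble::tibble(label = c("A", "B"), auc = c(0.6, 0.8),
                       se = c(0.1, 0.1))
  m <- pool_random_effects(st, "auc", "se", label = "label")
  fd <- forest_data(m)
  expect_equal(nrow(fd), 3)
  expect_equal(fd$row_type, c("study", "study", "pooled"))
  expect_equal(fd$effect[3], m$pooled)
  cap <- attr(fd, "caption")
  expect_equal(cap$q, 2)
  expect_equal(round(cap$p_heterogeneity, 4), 0.1573)
  expect_equal(tidy(m)$effect, fd$effect)
  g <- glance(m)
  expect_equal(g$pooled, m$pooled)
  expect_equal(g$n_studies, 2L)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})

test_that("degenerate meta-analytic inputs are rejected or warned", {
  expect_error(
    pool_random_effects(tibble::tibble(auc = c(0.5, 0.6), se = c(0, 0.1)),
                        "auc", "se"),
    "positive"
  )
  expect_warning(
    single <- pool_random_effects(tibble::tibble(auc = 0.7, se = 0.05),
                                  "auc", "se"),
    "single study"
  )
  expect_equal(single$pooled, 0.7)
  expect_equal(single$df, 0L)
})
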