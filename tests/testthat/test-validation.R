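test_that("goodness of fit reproduces the published p-values from printed counts", {
  obs <- c(940, 281, 414, 667, 32, 88)
  prd <- c(1151, 366, 442, 670, 28, 40)
  p <- goodness_of_fit(obs, prd)$p
  expect_equal(signif(p[1], 2), 5.0e-10)
  expect_equal(signif(p[2], 2), 8.9e-6)
  expect_equal(round(p[3], 3), 0.183)
  expect_equal(round(p[4], 3), 0.908)
  expect_equal(round(p[5], 3), 0.450)
  expect_equal(signif(p[6], 2), 3.2e-14)
})

test_that("the observed-count denominator convention is rejected by the same oracle", {
  # (observed - predicted)^2 / observed does NOT reproduce the printed values
  p_alt <- stats::pchisq((940 - 1151)^2 / 940, 1, lower.tail = FALSE)
  expect_false(signif(p_alt, 2) == 5.0e-10)
  p_alt2 <- stats::pchisq((414 - 442)^2 / 414, 1, lower.tail = FALSE)
  expect_false(round(p_alt2, 3) == 0.183)
})

test_that("goodness of fit handles the exact-fit and degenerate cases", {
  g <- goodness_of_fit(123, 123)
  expect_equal(g$chi2, 0)
  expect_equal(g$p, 1)
  expect_error(goodness_of_fit(10, 0), "positive")
  expect_error(goodness_of_fit(10, -3), "positive")
})

test_that("relative over-estimation matches the published calibration ratios", {
  expect_equal(round(calibration_row(940, 1151)$relative_error_pct, 1), 22.4)
  expect_equal(round(calibration_row(695, 808)$relative_error_pct, 1), 16.3)
})

test_that("expected deaths are exact for degenerate and constant-hazard models", {
  co <- rbind(patient_record(followup_time = 8),
              patient_record(id = 2L, followup_time = 3, died = 1L,
                             cause = "breast", diagnosis_year = 2008))
  expect_equal(expected_deaths(co, flat_model(0, 0), "breast")$expected, 0)

  lam <- 0.05
  m <- flat_model(lam, 0)
  one <- patient_record(followup_time = 7)
  expect_equal(expected_deaths(one, m, "breast")$expected,
               1 - exp(-lam * 7), tolerance = 1e-9)
  # a death is evaluated at its potential follow-up, not its death time
  dead <- patient_record(died = 1L, cause = "breast", followup_time = 2,
                         diagnosis_year = 2005)
  ed <- expected_deaths(dead, m, "breast", censor_date = 2015)
  expect_equal(ed$expected, 1 - exp(-lam * 10), tolerance = 1e-9)
})

test_that("validating the generating model on its own cohort is calibrated", {
  m23 <- synthetic_model_v23()
  gen <- generate_nz_like(nz_config(n = 6000), m23, seed = 41)
  v <- followup_window(assign_nz_treatments(gen$cohort, "primary"))
  for (cause in c("breast", "other")) {
    ed <- expected_deaths(v, m23, cause)$expected
    obs <- if (cause == "breast") sum(v$event_breast)
           else sum(v$died == 1 & v$cause == "other" & v$followup_time <= 15)
    expect_lt(abs(ed / obs - 1), 0.15)
    expect_gt(goodness_of_fit(obs, ed)$p, 0.01)
  }
})

test_that("calibration tables sum subgroups to the total row", {
  m23 <- synthetic_model_v23()
  gen <- generate_nz_like(nz_config(n = 3000), m23, seed = 8)
  v <- assign_nz_treatments(gen$cohort, "primary")
  tab <- calibration_table(v, list(v2.3 = m23), cause = "breast",
                           by = "ethnicity")
  total <- tab[tab$group == "total", ]
  parts <- tab[tab$group != "total", ]
  expect_equal(sum(parts$observed), total$observed)
  expect_equal(sum(parts$predicted_v2.3), total$predicted_v2.3,
               tolerance = 1e-9)
  expect_equal(sum(parts$n), total$n)
})

test_that("AUC equals the exhaustive pairwise U-statistic", {
  expect_equal(auc_15yr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_15yr(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  set.seed(50)
  for (i in 1:5) {
    scores <- round(runif(50), 2)  # rounding forces some ties
    outcomes <- rbinom(50, 1, 0.4)
    if (sum(outcomes) %in% c(0, 50)) next
    expect_equal(auc_15yr(scores, outcomes), auc_pairwise(scores, outcomes),
                 tolerance = 1e-12)
  }
  # invariance under monotone transform of the scores
  scores <- runif(40); outcomes <- rbinom(40, 1, 0.5)
  expect_equal(auc_15yr(scores, outcomes), auc_15yr(qlogis(scores), outcomes))
})

test_that("DeLong comparison is symmetric and matches pROC on a small instance", {
  set.seed(77)
  n <- 30
  outcomes <- rbinom(n, 1, 0.5)
  a <- runif(n) + outcomes * 0.8
  b <- a + rnorm(n, 0, 0.4)
  res_ab <- delong_compare(a, b, outcomes)
  res_ba <- delong_compare(b, a, outcomes)
  expect_equal(res_ab$p, res_ba$p)
  expect_equal(res_ab$diff, -res_ba$diff)
  expect_equal(res_ab$auc_a, auc_pairwise(a, outcomes))

  # independent implementation cross-check
  pr <- pROC::roc.test(pROC::roc(outcomes, a, quiet = TRUE),
                       pROC::roc(outcomes, b, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(res_ab$p, pr$p.value, tolerance = 1e-10)
})

test_that("identical rankings give a zero difference with p = 1", {
  set.seed(5)
  outcomes <- rbinom(40, 1, 0.5)
  a <- runif(40)
  expect_warning(res <- delong_compare(a, 2 * a, outcomes), "identical")
  expect_equal(res$diff, 0)
  expect_equal(res$p, 1)
})

test_that("DeLong p-values are roughly uniform under the null", {
  set.seed(321)
  ps <- replicate(60, {
    n <- 200
    outcomes <- rbinom(n, 1, 0.4)
    signal <- runif(n) + outcomes * 0.5
    a <- signal + rnorm(n, 0, 0.3)
    b <- signal + rnorm(n, 0, 0.3)   # same information content
    delong_compare(a, b, outcomes)$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.08)
  expect_gt(mean(ps), 0.35)
})

test_that("quintile calibration lies on the diagonal for self-generated data", {
  # full 15-year follow-up for everyone, so the simple observed proportion
  # estimates the same quantity as the predicted 15-year risk
  m23 <- synthetic_model_v23()
  cfg <- nz_config(n = 6000, year_range = c(2000, 2000), censor_date = 2016)
  gen <- generate_nz_like(cfg, m23, seed = 14)
  v <- assign_nz_treatments(gen$cohort, "primary")
  tab <- quintile_calibration(v, m23, horizon = 15)
  expect_equal(nrow(tab), 5L)
  expect_lte(max(tab$n) - min(tab$n), 1L)
  covered <- tab$mean_predicted >= tab$ci_lower &
    tab$mean_predicted <= tab$ci_upper
  expect_gte(sum(covered), 4L)
})

test_that("constant predictions collapse to a single informative bin", {
  m0 <- flat_model(0.02, 0.01)
  co <- do.call(rbind, lapply(1:40, function(i)
    patient_record(id = i, followup_time = 15,
                   died = as.integer(i <= 10),
                   cause = ifelse(i <= 10, "breast", ""))))
  tab <- quintile_calibration(co, m0, horizon = 15)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$observed, 0.25)
})

test_that("reclassification summarises the published percentage matrix", {
  tbl7 <- matrix(c(63.3, 1.2, 0,
                   1.0, 7.6, 1.2,
                   0, 0.8, 24.9), nrow = 3, byrow = TRUE)
  s <- reclassification_summary(tbl7)
  expect_equal(round(s$pct_changed, 1), 4.2)
  expect_equal(round(s$pct_up, 1), 2.4)
  expect_equal(round(s$pct_down, 1), 1.8)
})

test_that("reclassification counts a hand-built 20-patient example correctly", {
  old <- c(rep(0.10, 8), rep(0.17, 6), rep(0.30, 6))
  new <- c(rep(0.10, 6), 0.16, 0.22,          # 2 of the low group move up
           rep(0.17, 5), 0.12,                # 1 mid moves down
           rep(0.30, 6))
  rc <- reclassify(old, new)
  expect_equal(sum(rc$counts), 20)
  expect_equal(unname(diag(rc$counts)), c(6, 5, 6))
  expect_equal(rc$summary$pct_changed, 100 * 3 / 20)
  expect_equal(rc$summary$pct_up, 100 * 2 / 20)
  expect_equal(rc$summary$pct_down, 100 * 1 / 20)
  expect_equal(sum(rc$percent), 100)
})

test_that("threshold intervals are half-open with a closed top category", {
  rc <- reclassify(c(0.1499999, 0.15, 0.1999999, 0.20, 1.0),
                   c(0.1499999, 0.15, 0.1999999, 0.20, 1.0))
  expect_equal(unname(diag(rc$counts)), c(1, 2, 2))
  expect_equal(rc$summary$pct_changed, 0)
})

test_that("identical model versions produce an identity reclassification", {
  m23 <- synthetic_model_v23()
  gen <- generate_nz_like(nz_config(n = 500), m23, seed = 2)
  v <- assign_nz_treatments(gen$cohort, "primary")
  p10 <- predict_cumulative_mortality(v, m23, t = 10)$F_bc
  rc <- reclassify(p10, p10)
  expect_equal(rc$summary$pct_changed, 0)
  expect_equal(sum(diag(rc$counts)), nrow(v))
})
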