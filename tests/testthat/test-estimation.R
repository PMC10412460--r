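test_that("partial-likelihood fits match brute-force maximisation on tiny cohorts", {
  m22 <- synthetic_model_v22()
  for (seed in c(3, 17, 42, 101, 555)) {
    d <- tiny_estimation_cohort(seed)
    uni <- suppressWarnings(fit_univariable(d, "ER-positive"))
    df <- prbreast:::estimation_frame(d, "ER-positive")
    b_uni <- brute_force_beta(df$analysis_time, df$event_breast, df$pr_pos,
                              entry = df$entry_time, strat = df$study_id)
    if (abs(b_uni) < 3) expect_equal(uni$beta, b_uni, tolerance = 1e-6)

    off <- suppressWarnings(fit_pr_offset_cox(d, m22, "ER-positive"))
    pi_off <- prognostic_index(df, m22, "breast")
    b_off <- brute_force_beta(df$analysis_time, df$event_breast, df$pr_pos,
                              entry = df$entry_time, offset = pi_off,
                              strat = df$study_id)
    if (abs(b_off) < 3) expect_equal(off$beta, b_off, tolerance = 1e-6)
  }
})

test_that("Efron and Breslow agree on tie-free data and the oracle handles ties", {
  d <- tiny_estimation_cohort(7)
  d$followup_time <- d$followup_time + seq_len(nrow(d)) * 1e-4  # break ties
  ef <- fit_univariable(d, "ER-positive", ties = "efron")
  br <- fit_univariable(d, "ER-positive", ties = "breslow")
  expect_equal(ef$beta, br$beta, tolerance = 1e-8)

  # with genuine ties the oracle still matches coxph under each convention
  d$followup_time[d$died == 1] <- round(d$followup_time[d$died == 1])
  d$followup_time <- pmax(d$followup_time, d$entry_time + 0.05)
  for (ties in c("efron", "breslow")) {
    fit <- fit_univariable(d, "ER-positive", ties = ties)
    df <- prbreast:::estimation_frame(d, "ER-positive")
    b <- brute_force_beta(df$analysis_time, df$event_breast, df$pr_pos,
                          entry = df$entry_time, strat = df$study_id,
                          ties = ties)
    if (abs(b) < 3) expect_equal(fit$beta, b, tolerance = 1e-6)
  }
})

test_that("the offset truly constrains the prognostic-index coefficient", {
  m22 <- synthetic_model_v22()
  gen <- generate_bcac_like(bcac_config(n = 4000), m22, seed = 9)
  co <- impute_detection_mode(gen$cohort)
  d <- prbreast:::estimation_frame(co, "ER-positive")
  d$pi_offset <- prognostic_index(d, m22, "breast")
  fit1 <- survival::coxph(
    survival::Surv(entry_time, analysis_time, event_breast) ~ pr_pos +
      offset(pi_offset) + survival::strata(study_id), data = d)
  d$pi_offset2 <- 2 * d$pi_offset
  fit2 <- survival::coxph(
    survival::Surv(entry_time, analysis_time, event_breast) ~ pr_pos +
      offset(pi_offset2) + survival::strata(study_id), data = d)
  expect_gt(abs(coef(fit1)["pr_pos"] - coef(fit2)["pr_pos"]), 1e-4)
})

test_that("never-at-risk prevalent entries do not influence the fit", {
  d <- tiny_estimation_cohort(23, n = 10)
  last_event <- max(d$followup_time[d$died == 1 & d$cause == "breast"])
  extra <- d[1, ]
  extra$id <- 99L; extra$died <- 0L; extra$cause <- ""
  extra$entry_time <- last_event + 1; extra$followup_time <- last_event + 2
  f1 <- fit_univariable(rbind(d, extra), "ER-positive")
  extra$entry_time <- last_event + 3; extra$followup_time <- last_event + 4
  f2 <- fit_univariable(rbind(d, extra), "ER-positive")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$beta, fit_univariable(d, "ER-positive")$beta,
               tolerance = 1e-10)
})

test_that("a PR-independent outcome yields a null hazard ratio", {
  m22 <- synthetic_model_v22()
  cfg <- bcac_config(n = 6000,
                     true_pr_log_hr = c("ER-negative" = 0, "ER-positive" = 0))
  gen <- generate_bcac_like(cfg, m22, seed = 31)
  co <- impute_detection_mode(gen$cohort)
  est <- fit_pr_offset_cox(co, m22, "ER-positive")
  expect_lt(abs(est$beta), 3 * est$se)
  expect_true(est$ci_lower < 1 && est$ci_upper > 1 || abs(est$beta) < 3 * est$se)
})

test_that("hazard-ratio estimates are internally consistent", {
  gen <- generate_bcac_like(bcac_config(n = 5000), seed = 13)
  co <- impute_detection_mode(gen$cohort)
  est <- fit_univariable(co, "ER-positive")
  expect_equal(est$hr, exp(est$beta))
  expect_true(est$ci_lower < est$hr && est$hr < est$ci_upper)
  expect_lte(est$events, est$n)
})

test_that("the full multivariable model recovers generating coefficients", {
  # nodes enter generation via log1p with coefficient 0.55; at the fixture's
  # node range the per-node linearisation is roughly 0.55/(1+nodes_ref);
  # instead of a loose slope check, verify sign and significance of each
  # known risk factor and the PR estimate against its truth
  gen <- generate_bcac_like(bcac_config(n = 30000), seed = 61)
  co <- impute_detection_mode(gen$cohort)
  tab <- fit_full_multivariable(co, "ER-positive")
  rows <- function(nm) tab[tab$term == nm, ]
  expect_lt(abs(rows("pr_pos")$beta - log(0.72)), 3 * rows("pr_pos")$se)
  expect_gt(rows("tumour_size")$beta, 0)
  expect_gt(rows("positive_nodes")$beta, 0)
  expect_gt(rows("grade3")$beta, rows("grade2")$beta)
  expect_lt(rows("screen")$beta, 0)
  expect_lt(rows("grade3")$p, 1e-4)
})

test_that("interaction tests reject a strong simulated interaction and not a null", {
  m22 <- synthetic_model_v22()
  build <- function(seed, b_int) {
    set.seed(seed)
    n <- 4000
    d <- do.call(rbind, lapply(seq_len(n), function(i) patient_record(id = i)))
    d$study_id <- sample(1:3, n, TRUE)
    d$pr <- sample(c("negative", "positive"), n, TRUE)
    d$her2 <- sample(c("negative", "positive"), n, TRUE)
    pr <- as.integer(d$pr == "positive")
    h2 <- as.integer(d$her2 == "positive")
    # HER2 also acts through the model's own biomarker term; the extra
    # pieces below are the departure being tested for
    lam <- 0.08 * exp(-0.3 * pr + 0.1 * h2 + b_int * pr * h2)
    tt <- rexp(n, lam)
    d$followup_time <- pmin(tt, 15)
    d$died <- as.integer(tt <= 15)
    d$cause <- ifelse(d$died == 1, "breast", "")
    d
  }
  strong <- interaction_test(build(5, 0.8), m22, "ER-positive",
                             modifier = "HER2")
  expect_lt(strong$p, 0.01)
  null_p <- vapply(1:8, function(s)
    interaction_test(build(100 + s, 0), m22, "ER-positive",
                     modifier = "HER2")$p, 0)
  expect_gt(mean(null_p > 0.05), 0.5)
  expect_gt(min(null_p), 1e-4)

  # Wald and likelihood-ratio flavours agree on a moderate effect
  w <- interaction_test(build(5, 0.8), m22, "ER-positive", modifier = "HER2",
                        method = "lrt")
  expect_lt(abs(log10(w$p) - log10(strong$p)), 1)
})

test_that("Cochran's Q heterogeneity test matches hand arithmetic", {
  hom <- heterogeneity_test(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.15))
  expect_equal(hom$Q, 0)
  expect_equal(hom$p, 1)

  # 3-study hand example: w = 100 each, pooled = 0.3,
  # Q = 100*(0.04 + 0 + 0.04) = 8, df = 2
  het <- heterogeneity_test(c(0.1, 0.3, 0.5), c(0.1, 0.1, 0.1))
  expect_equal(het$Q, 8, tolerance = 1e-12)
  expect_equal(het$df, 2L)
  expect_equal(het$p, pchisq(8, 2, lower.tail = FALSE))
  expect_equal(het$pooled, 0.3)
})

test_that("heterogeneity type-I error is near nominal on homogeneous studies", {
  set.seed(97)
  rejections <- replicate(200, {
    k <- 8
    se <- runif(k, 0.1, 0.3)
    beta <- rnorm(k, -0.3, se)
    heterogeneity_test(beta, se)$p < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.05)
})

test_that("per-study estimates feed the heterogeneity test", {
  gen <- generate_bcac_like(bcac_config(n = 20000, n_studies = 8), seed = 19)
  co <- impute_detection_mode(gen$cohort)
  m22 <- synthetic_model_v22()
  tab <- per_study_estimates(co, m22, "ER-positive", min_events = 20)
  expect_gt(nrow(tab), 2)
  het <- heterogeneity_test(tab$beta, tab$se)
  expect_gt(het$p, 0.001)  # the generator is homogeneous across studies
})

test_that("Schoenfeld diagnostics flag time-varying effects and pass proportional ones", {
  d <- tiny_estimation_cohort(3, n = 10)
  fit <- suppressWarnings(fit_univariable(d, "ER-positive"))
  ph <- ph_diagnostics(fit)
  expect_true(all(is.finite(ph$table[, "p"])))
  expect_true(all(ph$table[, "p"] >= 0 & ph$table[, "p"] <= 1))

  # strongly time-varying effect: the x = 1 hazard starts high and drops,
  # so the log hazard ratio declines with time (piecewise inversion)
  set.seed(12)
  n <- 400
  x <- rep(0:1, each = n / 2)
  e <- rexp(n)
  t1 <- ifelse(e < 2, e / 2, 1 + (e - 2) / 0.2)   # rate 2 then 0.2 after t=1
  t0 <- e / 0.5                                    # constant rate 0.5
  tt <- pmin(ifelse(x == 1, t1, t0), 10)
  dd <- data.frame(time = tt, status = as.integer(tt < 10), x = x)
  cf <- survival::coxph(survival::Surv(time, status) ~ x, data = dd)
  ph2 <- ph_diagnostics(cf)
  expect_lt(ph2$table["x", "p"], 1e-6)
})

test_that("estimation fails informatively without events", {
  d <- tiny_estimation_cohort(3)
  d$died <- 0L; d$cause <- ""
  expect_error(fit_univariable(d, "ER-positive"), "no breast-cancer deaths")
})
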