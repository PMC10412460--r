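# independent oracles and small fixture builders used across test files

# hand-coded Cox partial log-likelihood (single covariate) with delayed
# entry, stratification, an offset and Efron or Breslow tie handling --
# maximised by golden-section search as a brute-force reference
pl_loglik <- function(beta, time, status, x,
                      entry = rep(0, length(time)),
                      offset = rep(0, length(time)),
                      strat = rep(1L, length(time)),
                      ties = "efron") {
  eta <- beta * x + offset
  ll <- 0
  for (s in unique(strat)) {
    idx <- which(strat == s)
    for (t in sort(unique(time[idx][status[idx] == 1]))) {
      D <- idx[time[idx] == t & status[idx] == 1]
      R <- idx[entry[idx] < t & time[idx] >= t]
      d <- length(D)
      sumR <- sum(exp(eta[R]))
      sumD <- sum(exp(eta[D]))
      ll <- ll + sum(eta[D])
      for (l in seq_len(d) - 1)
        ll <- ll - log(sumR - (if (ties == "efron") (l / d) * sumD else 0))
    }
  }
  ll
}

brute_force_beta <- function(time, status, x, entry = rep(0, length(time)),
                             offset = rep(0, length(time)),
                             strat = rep(1L, length(time)), ties = "efron") {
  stats::optimize(function(b) pl_loglik(b, time, status, x, entry, offset,
                                        strat, ties),
                  interval = c(-6, 6), maximum = TRUE, tol = 1e-12)$maximum
}

# exhaustive O(n^2) Mann-Whitney AUC
auc_pairwise <- function(scores, outcomes) {
  x <- scores[outcomes == 1]
  y <- scores[outcomes == 0]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# fine-grained numerical integration of the competing-risk cumulative
# incidence F_1(t) = int_0^t lambda_1(u) S(u) du for constant hazards
cif_integration <- function(lam1, lam2, t, steps = 10000) {
  u <- seq(0, t, length.out = steps + 1)
  du <- t / steps
  S <- exp(-(lam1 + lam2) * u)
  # trapezoidal rule on lambda_1 * S
  f <- lam1 * S
  sum((f[-1] + f[-length(f)]) / 2) * du
}

# one-row patient record with sensible defaults, overridable per test
patient_record <- function(...) {
  rec <- data.frame(
    id = 1L, study_id = 1L, diagnosis_year = 2005, age = 57,
    tumour_size = 1.449^2, grade = "2", positive_nodes = expm1(0.788),
    er = "positive", pr = "negative", her2 = "missing", ki67 = "missing",
    detection = "clinical", chemo = "none", hormone = "no",
    trastuzumab = FALSE, entry_time = 0, followup_time = 10, died = 0L,
    cause = "", stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  rec
}

# a model with constant cause-specific hazards and no covariate effects:
# exact closed forms exist for everything downstream
flat_model <- function(lambda_bc = 0.02, lambda_oth = 0.01) {
  m <- synthetic_model_v22()
  for (s in c("ER-negative", "ER-positive")) {
    m$strata[[s]]$breast <- list(terms = list(), biomarkers = list())
    m$strata[[s]]$other <- list(terms = list(), biomarkers = list())
    m$baseline[[s]]$breast <- lambda_bc * (0:15)
    m$baseline[[s]]$other <- lambda_oth * (0:15)
  }
  m
}

# random small estimation cohort with guaranteed events and PR variation
tiny_estimation_cohort <- function(seed, n = 9) {
  set.seed(seed)
  repeat {
    d <- data.frame(
      id = seq_len(n), study_id = sample(1:2, n, replace = TRUE),
      diagnosis_year = 2000, age = round(runif(n, 35, 75), 1),
      tumour_size = round(runif(n, 0.5, 6), 2), grade = sample(c("1", "2", "3"), n, TRUE),
      positive_nodes = rpois(n, 1.5), er = "positive",
      pr = sample(c("negative", "positive"), n, TRUE),
      her2 = sample(c("negative", "positive", "missing"), n, TRUE),
      ki67 = "missing", detection = sample(c("clinical", "screen"), n, TRUE),
      chemo = "none", hormone = "no", trastuzumab = FALSE,
      entry_time = round(ifelse(runif(n) < 0.3, runif(n, 0, 1.5), 0), 3),
      followup_time = round(runif(n, 0.2, 14), 3),
      died = rbinom(n, 1, 0.6), cause = "", stringsAsFactors = FALSE
    )
    d$followup_time <- pmax(d$followup_time, d$entry_time + 0.1)
    d$cause <- ifelse(d$died == 1, sample(c("breast", "other"), n, TRUE,
                                          prob = c(0.8, 0.2)), "")
    ok <- sum(d$died == 1 & d$cause == "breast") >= 3 &&
      length(unique(d$pr)) == 2 &&
      any(d$died == 1 & d$cause == "breast" & d$pr == "positive") &&
      any(d$died == 1 & d$cause == "breast" & d$pr == "negative")
    if (ok) return(d)
  }
}
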