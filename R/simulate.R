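## seeded synthetic cohort generators with known ground truth
##
## One top-level seed fans out to named sub-streams per component (covariates,
## missingness, treatments, survival, ...) so adding a component does not
## perturb unrelated draws.  Survival times are drawn by exact inversion of
## the piecewise-constant cause-specific cumulative hazard implied by the
## model, so the generator itself has no discretisation bias.

substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (seq_along(utf8ToInt(name)) + 7L))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Configuration for the multi-study estimation-cohort generator
#'
#' Defaults emulate a large multi-study consortium of European patients with
#' early invasive breast cancer: 49 study strata; age 57.1 (sd 11.9) years
#' truncated to 25--85; tumour size mean 2.1 (sd 1.5) cm; grade mix
#' 19.5/48.7/31.8%; node counts with mean 1.2 and sd 2.7; joint ER/PR
#' prevalences ER-/PR- 16.6%, ER-/PR+ 2.6%, ER+/PR- 13.8%, ER+/PR+ 67.0%
#' (so PR positivity is 14% within ER-negative and 83% within ER-positive
#' disease); HER2 positivity 16.1% with 28.3% missing; detection mode
#' missing for 46.6% with about 10% screen-detected among observed;
#' diagnosis years 1990--2017; and true conditional PR log hazard ratios of
#' `log(0.77)` (ER-negative) and `log(0.72)` (ER-positive) acting on top of
#' the baseline model's prognostic index.
#'
#' @param n Number of patients.
#' @param n_studies Number of study strata.
#' @param age_mean,age_sd,age_range Age-at-diagnosis distribution.
#' @param size_mean,size_sd Tumour-size (cm) log-normal moments.
#' @param grade_probs Probabilities of grades 1--3 (sum to 1).
#' @param nodes_mean,nodes_sd Positive-node negative-binomial moments.
#' @param er_pr_joint Named probabilities of the four ER/PR cells
#'   (`er_neg_pr_neg`, `er_neg_pr_pos`, `er_pos_pr_neg`, `er_pos_pr_pos`).
#' @param her2_pos,her2_missing HER2 positivity and missingness rates.
#' @param ki67_pos,ki67_missing KI67 positivity and missingness rates.
#' @param detection_missing,screen_frac Detection-mode missingness and the
#'   screen fraction among observed values.
#' @param year_range Diagnosis calendar-year range.
#' @param end_of_study Administrative end of study (decimal year).
#' @param chemo_prob,hormone_prob_er_pos,hormone_prob_er_neg,trastuzumab_prob
#'   Treatment-assignment probabilities (trastuzumab among observed
#'   HER2-positive cases).
#' @param prevalent_frac,entry_mean Fraction of prevalent cases with delayed
#'   entry and the mean entry delay in years.
#' @param true_pr_log_hr Named vector of the true conditional PR
#'   (positive-versus-negative) log hazard ratios per ER stratum, added to
#'   the model prognostic index when simulating survival.  Set to zero when
#'   generating from a model that already carries a PR term.
#' @return A list of class `generator_config`.
#' @export
bcac_config <- function(n = 45088, n_studies = 49,
                        age_mean = 57.1, age_sd = 11.9, age_range = c(25, 85),
                        size_mean = 2.1, size_sd = 1.5,
                        grade_probs = c(0.195, 0.487, 0.318),
                        nodes_mean = 1.2, nodes_sd = 2.7,
                        er_pr_joint = c(er_neg_pr_neg = 0.166,
                                        er_neg_pr_pos = 0.026,
                                        er_pos_pr_neg = 0.138,
                                        er_pos_pr_pos = 0.670),
                        her2_pos = 0.161, her2_missing = 0.283,
                        ki67_pos = 0.55, ki67_missing = 0.75,
                        detection_missing = 0.466, screen_frac = 0.101,
                        year_range = c(1990, 2017), end_of_study = 2018,
                        chemo_prob = 0.455,
                        hormone_prob_er_pos = 0.90, hormone_prob_er_neg = 0.20,
                        trastuzumab_prob = 0.60,
                        prevalent_frac = 0.30, entry_mean = 1.5,
                        true_pr_log_hr = c("ER-negative" = log(0.77),
                                           "ER-positive" = log(0.72))) {
  cfg <- as.list(environment())
  cfg$kind <- "bcac"
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

#' Configuration for the registry validation-cohort generator
#'
#' Defaults emulate a population-based registry of early invasive breast
#' cancer: diagnoses 2000--2014 with administrative censoring at
#' 2014-12-31; ethnicity strata (Maori 9.3%, Pacific 5.9%, European 72.3%,
#' other 11.1%, missing 1.5%); no missing detection mode (42.7%
#' screen-detected); 35% chemotherapy recorded only as a yes/no flag and no
#' trastuzumab record at all, so treatment-assumption rules must be applied
#' before prediction.  Survival is generated under the supplied model with
#' the primary treatment-assumption policy, with no extra PR effect.
#'
#' @inheritParams bcac_config
#' @param ethnicity_probs Named ethnic-strata probabilities.
#' @param censor_date Administrative censor date (decimal year).
#' @return A list of class `generator_config`.
#' @export
nz_config <- function(n = 11365,
                      age_mean = 57.1, age_sd = 12.2, age_range = c(25, 85),
                      size_mean = 2.3, size_sd = 1.7,
                      grade_probs = c(0.250, 0.467, 0.283),
                      nodes_mean = 1.7, nodes_sd = 3.4,
                      er_pr_joint = c(er_neg_pr_neg = 0.178,
                                      er_neg_pr_pos = 0.015,
                                      er_pos_pr_neg = 0.139,
                                      er_pos_pr_pos = 0.668),
                      her2_pos = 0.156, her2_missing = 0.19,
                      ki67_pos = 0.55, ki67_missing = 1,
                      detection_missing = 0, screen_frac = 0.427,
                      ethnicity_probs = c(maori = 0.093, pacific = 0.059,
                                          european = 0.723, other = 0.110,
                                          missing = 0.015),
                      year_range = c(2000, 2014),
                      censor_date = decimal_year("2014-12-31"),
                      chemo_prob = 0.35,
                      hormone_prob_er_pos = 0.75, hormone_prob_er_neg = 0.05) {
  cfg <- as.list(environment())
  cfg$kind <- "nz"
  cfg$prevalent_frac <- 0
  cfg$entry_mean <- 0
  cfg$true_pr_log_hr <- c("ER-negative" = 0, "ER-positive" = 0)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n) || cfg$n < 1)
    stop("config: n must be >= 1", call. = FALSE)
  if (abs(sum(cfg$er_pr_joint) - 1) > 1e-8)
    stop("config: ER/PR joint prevalences must sum to 1", call. = FALSE)
  if (abs(sum(cfg$grade_probs) - 1) > 1e-8)
    stop("config: grade probabilities must sum to 1", call. = FALSE)
  probs <- c(cfg$er_pr_joint, cfg$grade_probs, cfg$her2_pos, cfg$her2_missing,
             cfg$ki67_pos, cfg$ki67_missing, cfg$detection_missing,
             cfg$screen_frac, cfg$chemo_prob, cfg$hormone_prob_er_pos,
             cfg$hormone_prob_er_neg, cfg$prevalent_frac %||% 0)
  if (any(probs < 0 | probs > 1))
    stop("config: probabilities must lie in [0, 1]", call. = FALSE)
  if (!is.null(cfg$ethnicity_probs) &&
      abs(sum(cfg$ethnicity_probs) - 1) > 1e-8)
    stop("config: ethnicity probabilities must sum to 1", call. = FALSE)
  invisible(cfg)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out < lo | out > hi))
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

rlnorm_capped <- function(n, mean, sd, cap) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  out <- stats::rlnorm(n, meanlog, sdlog)
  while (any(bad <- out > cap))
    out[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  out
}

draw_covariates <- function(cfg, seed) {
  n <- cfg$n
  d <- with_seed(substream_seed(seed, "covariates"), {
    cells <- sample(names(cfg$er_pr_joint), n, replace = TRUE,
                    prob = cfg$er_pr_joint)
    data.frame(
      id = seq_len(n),
      age = round(rtrunc_norm(n, cfg$age_mean, cfg$age_sd,
                              cfg$age_range[1], cfg$age_range[2]), 1),
      tumour_size = round(rlnorm_capped(n, cfg$size_mean, cfg$size_sd, 20), 2),
      grade = sample(c("1", "2", "3"), n, replace = TRUE,
                     prob = cfg$grade_probs),
      positive_nodes = pmin(stats::rnbinom(
        n, mu = cfg$nodes_mean,
        size = cfg$nodes_mean^2 / max(cfg$nodes_sd^2 - cfg$nodes_mean, 1e-6)), 20L),
      er = ifelse(grepl("^er_pos", cells), "positive", "negative"),
      pr = ifelse(grepl("pr_pos$", cells), "positive", "negative"),
      diagnosis_year = round(stats::runif(n, cfg$year_range[1],
                                          cfg$year_range[2] + 1), 3),
      stringsAsFactors = FALSE
    )
  })
  d$diagnosis_year <- pmin(d$diagnosis_year, cfg$year_range[2] + 0.999)
  d
}

draw_biomarkers <- function(d, cfg, seed) {
  n <- nrow(d)
  with_seed(substream_seed(seed, "biomarkers"), {
    her2 <- ifelse(stats::runif(n) < cfg$her2_pos, "positive", "negative")
    her2[stats::runif(n) < cfg$her2_missing] <- "missing"
    ki67 <- ifelse(stats::runif(n) < cfg$ki67_pos, "positive", "negative")
    ki67[stats::runif(n) < cfg$ki67_missing] <- "missing"
    d$her2 <- her2
    d$ki67 <- ki67
  })
  with_seed(substream_seed(seed, "detection"), {
    det <- ifelse(stats::runif(n) < cfg$screen_frac, "screen", "clinical")
    det[stats::runif(n) < cfg$detection_missing] <- "missing"
    d$detection <- det
  })
  d
}

## survival by exact inversion of the yearly piecewise-constant hazard
simulate_survival <- function(rate_bc, rate_oth, seed) {
  n <- nrow(rate_bc)
  rate_tot <- rate_bc + rate_oth
  U <- upper.tri(diag(15), diag = TRUE) * 1   # row-wise cumulative sums
  cum_tot <- cbind(0, rate_tot %*% U)
  with_seed(substream_seed(seed, "survival"), {
    draw_times <- function(idx) {
      e <- stats::rexp(length(idx))
      t_out <- rep(Inf, length(idx))
      cause <- rep(NA_character_, length(idx))
      for (j in 1:15) {
        lo <- cum_tot[idx, j]; hi <- cum_tot[idx, j + 1]
        hit <- is.infinite(t_out) & e >= lo & e < hi
        if (any(hit)) {
          rj <- rate_tot[idx, j][hit]
          t_out[hit] <- (j - 1) + (e[hit] - lo[hit]) / rj
          p_bc <- rate_bc[idx, j][hit] / rj
          cause[hit] <- ifelse(stats::runif(sum(hit)) < p_bc, "breast", "other")
        }
      }
      list(time = t_out, cause = cause)
    }
    draw_times(seq_len(n))
  })
}

generate_core <- function(cfg, seed) {
  d <- draw_covariates(cfg, seed)
  d <- draw_biomarkers(d, cfg, seed)
  d$study_id <- if (cfg$kind == "bcac") {
    w <- with_seed(substream_seed(seed, "studies"),
                   stats::rlnorm(cfg$n_studies, 0, 0.8))
    with_seed(substream_seed(seed, "study_assign"),
              sample(seq_len(cfg$n_studies), nrow(d), replace = TRUE,
                     prob = w / sum(w)))
  } else 1L
  if (!is.null(cfg$ethnicity_probs))
    d$ethnicity <- with_seed(substream_seed(seed, "ethnicity"),
                             sample(names(cfg$ethnicity_probs), nrow(d),
                                    replace = TRUE, prob = cfg$ethnicity_probs))
  ## treatments
  n <- nrow(d)
  with_seed(substream_seed(seed, "treatments"), {
    on_chemo <- stats::runif(n) < cfg$chemo_prob
    p_h <- ifelse(d$er == "positive", cfg$hormone_prob_er_pos,
                  cfg$hormone_prob_er_neg)
    d$hormone <- ifelse(stats::runif(n) < p_h, "yes", "no")
    if (cfg$kind == "bcac") {
      d$chemo <- ifelse(on_chemo,
                        ifelse(d$diagnosis_year < 2005, "anthracycline",
                               "taxane"), "none")
      d$trastuzumab <- d$her2 == "positive" & d$diagnosis_year > 2005 &
        stats::runif(n) < cfg$trastuzumab_prob
    } else {
      d$chemo <- ifelse(on_chemo, "yes", "no")
      d$trastuzumab <- NA
    }
  })
  d
}

#' Generate a multi-study estimation cohort with known ground truth
#'
#' Draws covariates, biomarkers (with missingness), study membership and
#' treatments from `config`, computes each patient's prognostic index under
#' `model` exactly as the estimation pipeline would (detection mode
#' mean-imputed with the same rule), adds the configured true conditional PR
#' log hazard ratio to the breast-cause linear predictor, and simulates
#' cause-specific survival by exact inversion of the yearly
#' piecewise-constant hazards.  Prevalent cases receive a delayed entry time
#' and their survival is redrawn conditional on being alive at entry, so
#' left-truncated risk sets are the correct likelihood.
#'
#' @param config A [bcac_config()].
#' @param model The baseline [pb_model()] (default [synthetic_model_v22()]).
#' @param seed Integer seed; the run is a pure function of
#'   `(config, model, seed)`.
#' @return A list with `cohort` (data frame in the standard schema) and
#'   `truth` (the config, the true PR log hazard ratios and the model
#'   version).
#' @export
generate_bcac_like <- function(config, model = synthetic_model_v22(),
                               seed = 1L) {
  stopifnot(inherits(config, "generator_config"),
            identical(config$kind, "bcac"))
  d <- generate_core(config, seed)
  n <- nrow(d)

  sim <- d
  sim <- impute_detection_mode(sim)  # same rule the pipeline applies
  pi_bc <- prognostic_index(sim, model, "breast") +
    ifelse(sim$pr == "positive",
           config$true_pr_log_hr[stratum_of(sim$er)], 0)
  pi_oth <- prognostic_index(sim, model, "other")
  rx <- treatment_rh(sim, model)

  strat <- stratum_of(d$er)
  inc <- function(cause) {
    m <- rbind("ER-negative" = diff(model$baseline[["ER-negative"]][[cause]]),
               "ER-positive" = diff(model$baseline[["ER-positive"]][[cause]]))
    m[strat, , drop = FALSE]
  }
  rate_bc <- inc("breast") * exp(pi_bc) * rx
  rate_oth <- inc("other") * exp(pi_oth)

  surv <- simulate_survival(rate_bc, rate_oth, seed)

  d$entry_time <- 0
  prevalent <- with_seed(substream_seed(seed, "entry"),
                         stats::runif(n) < config$prevalent_frac)
  entry <- with_seed(substream_seed(seed, "entry_delay"),
                     pmin(stats::rexp(n, 1 / max(config$entry_mean, 1e-9)), 12))
  d$entry_time[prevalent] <- round(entry[prevalent], 3)

  ## prevalent sampling: redraw survival conditional on being alive at entry
  k <- 0L
  while (any(bad <- surv$time <= d$entry_time) && k < 1000L) {
    k <- k + 1L
    redo <- simulate_survival(rate_bc[bad, , drop = FALSE],
                              rate_oth[bad, , drop = FALSE],
                              seed = substream_seed(seed, paste0("redraw", k)))
    surv$time[bad] <- redo$time
    surv$cause[bad] <- redo$cause
  }
  if (any(surv$time <= d$entry_time))
    stop("could not generate survival past entry for some prevalent cases",
         call. = FALSE)

  censor <- pmin(config$end_of_study - d$diagnosis_year, 15)
  censor <- pmax(censor, d$entry_time + 0.01)
  died <- is.finite(surv$time) & surv$time <= censor
  d$followup_time <- pmax(round(ifelse(died, surv$time, censor), 4),
                          d$entry_time + 0.001)
  d$died <- as.integer(died)
  d$cause <- ifelse(died, surv$cause, "")
  d <- d[, intersect(c(cohort_required_cols, cohort_optional_cols), names(d))]
  list(cohort = d,
       truth = list(config = config, pr_log_hr = config$true_pr_log_hr,
                    model_version = model$version))
}

#' Generate a registry-style validation cohort
#'
#' As [generate_bcac_like()] but emulating a population registry: single
#' study, ethnicity labels, administrative censoring at the configured
#' censor date, no delayed entry and no extra PR effect -- survival is
#' generated under `model` itself (so validating `model` on its own cohort
#' should be well calibrated).  Chemotherapy is recorded only as a
#' `yes`/`no` flag and trastuzumab is not recorded: the generator resolves
#' treatments internally with the primary assumption policy
#' (see [assign_nz_treatments()]), which the validation pipeline must apply
#' to reproduce them.
#'
#' @param config An [nz_config()].
#' @param model The [pb_model()] generating (and later validated on) the
#'   cohort.
#' @param seed Integer seed.
#' @return A list with `cohort` and `truth`.
#' @export
generate_nz_like <- function(config, model = synthetic_model_v23(),
                             seed = 1L) {
  stopifnot(inherits(config, "generator_config"), identical(config$kind, "nz"))
  d <- generate_core(config, seed)

  resolved <- assign_nz_treatments(d, policy = "primary")
  pi_bc <- prognostic_index(resolved, model, "breast")
  pi_oth <- prognostic_index(resolved, model, "other")
  rx <- treatment_rh(resolved, model)

  strat <- stratum_of(d$er)
  inc <- function(cause) {
    m <- rbind("ER-negative" = diff(model$baseline[["ER-negative"]][[cause]]),
               "ER-positive" = diff(model$baseline[["ER-positive"]][[cause]]))
    m[strat, , drop = FALSE]
  }
  rate_bc <- inc("breast") * exp(pi_bc) * rx
  rate_oth <- inc("other") * exp(pi_oth)
  surv <- simulate_survival(rate_bc, rate_oth, seed)

  censor <- pmax(pmin(config$censor_date - d$diagnosis_year, 15), 1e-3)
  died <- is.finite(surv$time) & surv$time <= censor
  d$entry_time <- 0
  d$followup_time <- round(ifelse(died, surv$time, censor), 4)
  d$died <- as.integer(died)
  d$cause <- ifelse(died, surv$cause, "")
  d <- d[, intersect(c(cohort_required_cols, cohort_optional_cols), names(d))]
  list(cohort = d,
       truth = list(config = config, model_version = model$version))
}

#' Breast-cancer deaths per 1000 person-years
#'
#' Crude event rate over the 15-year analysis window; a quick sanity check
#' on generator calibration.
#'
#' @param cohort Patient data frame.
#' @param horizon Analysis horizon (default 15 years).
#' @return Deaths per 1000 person-years.
#' @export
event_rate_per_1000py <- function(cohort, horizon = 15) {
  at <- pmin(cohort$followup_time, horizon)
  ev <- cohort$died == 1L & as.character(cohort$cause) %in% "breast" &
    cohort$followup_time <= horizon
  1000 * sum(ev) / sum(at - pmin(cohort$entry_time, at))
}
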