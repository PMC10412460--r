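## study-stratified, left-truncated Cox estimation of the PR effect

#' @importFrom survival Surv coxph strata cox.zph
NULL

hr_estimate <- function(fit, parm, stratum, flavour, n, events) {
  beta <- unname(stats::coef(fit)[parm])
  se <- sqrt(diag(stats::vcov(fit)))[parm]
  structure(
    list(beta = beta, se = unname(se), hr = exp(beta),
         ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
         p = 2 * stats::pnorm(-abs(beta / se)),
         n = n, events = events, stratum = stratum, flavour = flavour,
         fit = fit),
    class = "hr_estimate"
  )
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("%s, %s\n", x$flavour, x$stratum))
  cat(sprintf("  HR %.2f (95%% CI %.2f-%.2f), p = %.3g; beta = %.4f (SE %.4f)\n",
              x$hr, x$ci_lower, x$ci_upper, x$p, x$beta, x$se))
  cat(sprintf("  n = %d, events = %d\n", x$n, x$events))
  invisible(x)
}

estimation_frame <- function(cohort, stratum, horizon = 15) {
  want <- stratum_of(cohort$er) == stratum
  d <- cohort[want, , drop = FALSE]
  if (!nrow(d)) stop("no records in stratum ", stratum, call. = FALSE)
  d <- followup_window(d, censor_date = Inf, horizon = horizon)
  d$event_breast <- as.integer(d$died == 1L &
                                 as.character(d$cause) %in% "breast" &
                                 d$followup_time <= horizon)
  d <- d[d$analysis_time > d$entry_time, , drop = FALSE]
  if (sum(d$event_breast) == 0L)
    stop("no breast-cancer deaths in stratum ", stratum,
         "; hazard ratio not estimable", call. = FALSE)
  d$pr_pos <- as.integer(as.character(d$pr) == "positive")
  d
}

#' Offset-adjusted hazard ratio for PR status
#'
#' Fits a Cox proportional-hazards model for breast-cancer-specific
#' mortality, stratified by study, with delayed entry (left truncation) and
#' censoring at 15 years, in which the baseline model's prognostic index
#' enters as an offset -- i.e. its coefficient is constrained to one -- and
#' the single free parameter is the PR-positive indicator.  This isolates
#' the biomarker's effect conditional on the existing model.
#'
#' @param cohort Eligible patient data frame (see [apply_eligibility()]).
#' @param model The baseline [pb_model()] used to compute the offset
#'   prognostic index (the biomarker being estimated must not be in it).
#' @param stratum `"ER-negative"` or `"ER-positive"`.
#' @param horizon Censoring horizon in years (default 15).
#' @param ties Tie handling passed to [survival::coxph()] (default Efron).
#' @return An object of class `hr_estimate` with `beta`, `se`, `hr`, Wald
#'   95% CI, `p`, `n`, `events`, `stratum`, `flavour` and the underlying
#'   `fit`.
#' @export
fit_pr_offset_cox <- function(cohort, model, stratum, horizon = 15,
                              ties = "efron") {
  d <- estimation_frame(cohort, stratum, horizon)
  d$pi_offset <- prognostic_index(d, model, "breast")
  if (any(!is.finite(d$pi_offset)))
    stop("non-finite prognostic index for row id(s): ",
         paste(utils::head(d$id[!is.finite(d$pi_offset)], 5), collapse = ", "),
         call. = FALSE)
  fit <- survival::coxph(
    Surv(entry_time, analysis_time, event_breast) ~ pr_pos +
      offset(pi_offset) + strata(study_id),
    data = d, ties = ties
  )
  hr_estimate(fit, "pr_pos", stratum, "offset-adjusted",
              nrow(d), sum(d$event_breast))
}

#' Univariable hazard ratio for PR status
#'
#' As [fit_pr_offset_cox()] but with no offset adjustment: the crude
#' study-stratified, left-truncated effect of PR positivity.
#'
#' @inheritParams fit_pr_offset_cox
#' @return An `hr_estimate`.
#' @export
fit_univariable <- function(cohort, stratum, horizon = 15, ties = "efron") {
  d <- estimation_frame(cohort, stratum, horizon)
  fit <- survival::coxph(
    Surv(entry_time, analysis_time, event_breast) ~ pr_pos + strata(study_id),
    data = d, ties = ties
  )
  hr_estimate(fit, "pr_pos", stratum, "univariable",
              nrow(d), sum(d$event_breast))
}

#' Full multivariable model with individual prognostic factors
#'
#' Frees the coefficients of all standard prognostic factors instead of
#' constraining them through the prognostic index: PR status, age per 5
#' years, size per cm, nodes per positive node, grade (2 and 3 versus 1),
#' screen versus clinical detection, and HER2 status.
#'
#' @inheritParams fit_pr_offset_cox
#' @return A data frame of class `hr_table`, one row per coefficient, with
#'   `term`, `beta`, `se`, `hr`, `ci_lower`, `ci_upper`, `p`, plus
#'   attributes `n`, `events`, `stratum`; the `coxph` fit is in attribute
#'   `fit`.
#' @export
fit_full_multivariable <- function(cohort, stratum, horizon = 15,
                                   ties = "efron") {
  d <- estimation_frame(cohort, stratum, horizon)
  d$age5 <- d$age / 5
  d$grade <- factor(as.character(d$grade), levels = c("1", "2", "3"))
  d$screen <- detection_screen_value(d)
  d$her2_pos <- as.integer(as.character(d$her2) == "positive")
  fit <- survival::coxph(
    Surv(entry_time, analysis_time, event_breast) ~ pr_pos + age5 +
      tumour_size + positive_nodes + grade + screen + her2_pos +
      strata(study_id),
    data = d, ties = ties
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  out <- data.frame(
    term = names(beta), beta = unname(beta), se = unname(se),
    hr = exp(unname(beta)),
    ci_lower = exp(unname(beta) - 1.96 * unname(se)),
    ci_upper = exp(unname(beta) + 1.96 * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se)))
  )
  attr(out, "n") <- nrow(d); attr(out, "events") <- sum(d$event_breast)
  attr(out, "stratum") <- stratum; attr(out, "fit") <- fit
  class(out) <- c("hr_table", "data.frame")
  out
}

#' Test a PR-by-modifier interaction
#'
#' Adds a product term between the PR-positive indicator and a modifier (age
#' per 5 years, or HER2 positivity) to the offset-adjusted model and reports
#' the Wald p-value for the interaction coefficient (likelihood-ratio
#' alternative by flag).
#'
#' @inheritParams fit_pr_offset_cox
#' @param modifier `"age"` or `"HER2"`.
#' @param method `"wald"` (default) or `"lrt"`.
#' @return A list with `p`, `beta`, `se`, `modifier`, `method`.
#' @export
interaction_test <- function(cohort, model, stratum,
                             modifier = c("age", "HER2"),
                             method = c("wald", "lrt"), horizon = 15) {
  modifier <- match.arg(modifier)
  method <- match.arg(method)
  d <- estimation_frame(cohort, stratum, horizon)
  d$pi_offset <- prognostic_index(d, model, "breast")
  d$mod <- if (modifier == "age") d$age / 5
           else as.integer(as.character(d$her2) == "positive")
  full <- survival::coxph(
    Surv(entry_time, analysis_time, event_breast) ~ pr_pos + mod +
      pr_pos:mod + offset(pi_offset) + strata(study_id),
    data = d, ties = "efron"
  )
  beta <- stats::coef(full)["pr_pos:mod"]
  se <- sqrt(diag(stats::vcov(full)))["pr_pos:mod"]
  p <- if (method == "wald") {
    2 * stats::pnorm(-abs(beta / se))
  } else {
    reduced <- survival::coxph(
      Surv(entry_time, analysis_time, event_breast) ~ pr_pos + mod +
        offset(pi_offset) + strata(study_id),
      data = d, ties = "efron"
    )
    stats::pchisq(2 * (full$loglik[2] - reduced$loglik[2]), df = 1,
                  lower.tail = FALSE)
  }
  list(p = unname(p), beta = unname(beta), se = unname(se),
       modifier = modifier, method = method)
}

#' Cochran's Q test for between-study heterogeneity
#'
#' Inverse-variance-weighted heterogeneity of study-specific log hazard
#' ratios: `Q = sum w_i (b_i - b_bar)^2` with `w_i = 1/se_i^2`, referred to
#' a chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param beta Numeric vector of study-specific log hazard ratios.
#' @param se Their standard errors.
#' @return A list with `Q`, `df`, `p`, `pooled` (the inverse-variance pooled
#'   log hazard ratio).
#' @export
heterogeneity_test <- function(beta, se) {
  stopifnot(length(beta) == length(se), length(beta) >= 2,
            all(is.finite(beta)), all(is.finite(se)), all(se > 0))
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - pooled)^2)
  df <- length(beta) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       pooled = pooled)
}

#' Study-specific PR log hazard ratios
#'
#' Fits the offset model separately within each study with enough events,
#' for use with [heterogeneity_test()] or a forest plot.
#'
#' @inheritParams fit_pr_offset_cox
#' @param min_events Minimum breast-cancer deaths for a study to be fitted.
#' @return Data frame with `study_id`, `beta`, `se`, `events`.
#' @export
per_study_estimates <- function(cohort, model, stratum, min_events = 10,
                                horizon = 15) {
  d <- estimation_frame(cohort, stratum, horizon)
  d$pi_offset <- prognostic_index(d, model, "breast")
  out <- lapply(split(d, d$study_id), function(sd) {
    if (sum(sd$event_breast) < min_events ||
        length(unique(sd$pr_pos)) < 2L) return(NULL)
    fit <- try(survival::coxph(
      Surv(entry_time, analysis_time, event_breast) ~ pr_pos +
        offset(pi_offset),
      data = sd, ties = "efron"), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    se <- sqrt(diag(stats::vcov(fit)))["pr_pos"]
    if (!is.finite(se) || se > 10) return(NULL)
    data.frame(study_id = sd$study_id[1], beta = unname(stats::coef(fit)["pr_pos"]),
               se = unname(se), events = sum(sd$event_breast))
  })
  do.call(rbind, out)
}

#' Proportional-hazards diagnostics
#'
#' Scaled Schoenfeld residuals against time with the standard
#' correlation-with-time test, via [survival::cox.zph()].
#'
#' @param est An `hr_estimate` (or a bare `coxph` fit).
#' @return A list with `table` (per-term chi-square and p), `residuals`
#'   (scaled Schoenfeld residuals, one row per event time) and `time`.
#' @export
ph_diagnostics <- function(est) {
  fit <- if (inherits(est, "hr_estimate")) est$fit else est
  stopifnot(inherits(fit, "coxph"))
  z <- survival::cox.zph(fit, transform = "identity")
  list(table = z$table, residuals = z$y, time = z$time, zph = z)
}
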