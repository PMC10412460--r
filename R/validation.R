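## external-validation statistics

#' Expected number of deaths under a model
#'
#' Sums, over patients, the predicted cumulative cause-specific mortality
#' evaluated at each patient's own horizon: observed follow-up for
#' survivors and *potential* follow-up (diagnosis to the administrative
#' censor date, as if the patient had survived) for deaths, all capped at
#' 15 years.  Run [followup_window()] first (or it is applied here with its
#' defaults).
#'
#' @param cohort Patient data frame with treatments resolved
#'   (see [assign_nz_treatments()]).
#' @param model A [pb_model()].
#' @param cause `"breast"`, `"other"` or `"all"`.
#' @param censor_date Administrative censor date (decimal year) used if the
#'   follow-up window columns are absent.
#' @return A list with `expected` (the predicted count) and `per_patient`
#'   (each patient's contribution).
#' @export
expected_deaths <- function(cohort, model, cause = c("breast", "other", "all"),
                            censor_date = decimal_year("2014-12-31")) {
  cause <- match.arg(cause)
  if (is.null(cohort$expected_horizon))
    cohort <- followup_window(cohort, censor_date = censor_date)
  pred <- predict_cumulative_mortality(cohort, model,
                                       t = cohort$expected_horizon,
                                       per_patient = TRUE)
  contrib <- switch(cause, breast = pred$F_bc, other = pred$F_oth,
                    all = pred$F_all)
  list(expected = sum(contrib), per_patient = contrib)
}

#' Chi-square goodness of fit for observed versus predicted deaths
#'
#' `chi2 = (observed - predicted)^2 / predicted`, referred to a chi-square
#' distribution with one degree of freedom.  The predicted (expected) count
#' is the denominator.
#'
#' @param observed Observed number of deaths.
#' @param predicted Model-predicted number of deaths (must be positive).
#' @return A list with `chi2`, `df` (= 1) and `p`.  Vectorised over pairs.
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (any(!is.finite(predicted)) || any(predicted <= 0))
    stop("predicted count must be positive", call. = FALSE)
  chi2 <- (observed - predicted)^2 / predicted
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Calibration summary for one grouping
#'
#' @param observed Observed deaths.
#' @param predicted Predicted deaths.
#' @return A one-row data frame with observed, predicted, relative
#'   over/under-estimation in percent (`(predicted - observed)/observed`),
#'   chi-square and p.
#' @export
calibration_row <- function(observed, predicted) {
  g <- goodness_of_fit(observed, predicted)
  data.frame(observed = observed, predicted = predicted,
             relative_error_pct = 100 * (predicted - observed) / observed,
             chi2 = g$chi2, p = g$p)
}

#' Observed-versus-predicted calibration table
#'
#' Builds a calibration report in the shape of a registry validation table:
#' one row per level of a grouping variable plus a total row, with observed
#' deaths, predicted deaths under each supplied model, relative error and
#' goodness of fit for the last model.  Subgroup predicted and observed
#' counts sum to the total row by construction.
#'
#' @param cohort Patient data frame (follow-up windows applied or appliable).
#' @param models Named list of [pb_model()] objects (e.g.
#'   `list("v2.2" = m22, "v2.3" = m23)`).
#' @param cause `"breast"`, `"other"` or `"all"`.
#' @param by Optional name of a grouping column (e.g. `"ethnicity"`).
#' @param censor_date Administrative censor date (decimal year).
#' @return A data frame of class `calibration_report`.
#' @export
calibration_table <- function(cohort, models, cause = "breast", by = NULL,
                              censor_date = decimal_year("2014-12-31")) {
  if (is.null(cohort$expected_horizon))
    cohort <- followup_window(cohort, censor_date = censor_date)
  obs_flag <- switch(cause,
    breast = cohort$died == 1L & as.character(cohort$cause) %in% "breast" &
      cohort$followup_time <= 15,
    other = cohort$died == 1L & !as.character(cohort$cause) %in% "breast" &
      cohort$followup_time <= 15,
    all = cohort$died == 1L & cohort$followup_time <= 15)
  preds <- lapply(models, function(m)
    expected_deaths(cohort, m, cause, censor_date)$per_patient)
  groups <- if (is.null(by)) rep("total", nrow(cohort))
            else as.character(cohort[[by]])
  levels_ <- unique(groups)
  rows <- lapply(c(levels_, if (!is.null(by)) "total"), function(g) {
    idx <- if (g == "total" && !is.null(by)) rep(TRUE, nrow(cohort))
           else groups == g
    obs <- sum(obs_flag[idx])
    prd <- vapply(preds, function(p) sum(p[idx]), 0)
    last <- prd[length(prd)]
    data.frame(group = g, n = sum(idx), observed = obs,
               as.list(stats::setNames(prd, paste0("predicted_", names(prd)))),
               relative_error_pct = 100 * (last - obs) / obs,
               chi2 = (obs - last)^2 / last,
               p = stats::pchisq((obs - last)^2 / last, 1, lower.tail = FALSE),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_report", "data.frame")
  out
}

## ------------------------------------------------------------------
## discrimination

#' Area under the ROC curve by the Mann-Whitney statistic
#'
#' Concordance between a predicted risk score and a binary outcome (death
#' from breast cancer within the window versus everyone else), with tied
#' scores counted half.
#'
#' @param scores Numeric predicted risks.
#' @param outcomes Binary outcome (0/1 or logical).
#' @return The AUC as a single number.
#' @export
auc_15yr <- function(scores, outcomes) {
  outcomes <- as.integer(as_flag(outcomes))
  stopifnot(length(scores) == length(outcomes))
  m <- sum(outcomes == 1L); n <- sum(outcomes == 0L)
  if (m == 0L || n == 0L)
    stop("AUC needs at least one case and one non-case", call. = FALSE)
  r <- rank(scores)
  (sum(r[outcomes == 1L]) - m * (m + 1) / 2) / (m * n)
}

## placement values: for each case, fraction of controls it beats (ties half),
## and vice versa -- the components of the DeLong variance
placements <- function(scores, outcomes) {
  x <- scores[outcomes == 1L]; y <- scores[outcomes == 0L]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Compare two correlated AUCs (DeLong's method)
#'
#' Both scores are evaluated on the same subjects; the variance of the AUC
#' difference is computed from the empirical covariance of the placement
#' values and the difference is referred to a standard normal (two sided).
#' If the two scorings rank the subjects identically, the difference is 0
#' and `p = 1` is returned with a warning.
#'
#' @param scores_a,scores_b Predicted risks under the two models.
#' @param outcomes Binary outcome shared by both.
#' @return A list with `auc_a`, `auc_b`, `diff`, `se`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, outcomes) {
  outcomes <- as.integer(as_flag(outcomes))
  stopifnot(length(scores_a) == length(outcomes),
            length(scores_b) == length(outcomes))
  pa <- placements(scores_a, outcomes)
  pb <- placements(scores_b, outcomes)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    if (abs(d) > 1e-12)
      warning("zero DeLong variance with unequal AUCs", call. = FALSE)
    else
      warning("identical score rankings; AUC difference is 0", call. = FALSE)
    return(list(auc_a = pa$auc, auc_b = pb$auc, diff = 0, se = 0,
                z = 0, p = 1))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = sqrt(var_diff),
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

## ------------------------------------------------------------------
## quintile calibration

wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = centre - half, upper = centre + half)
}

#' Calibration by quantile bins of predicted risk
#'
#' Bins patients by quantile of predicted cumulative breast-cancer mortality
#' at the horizon and, per bin, compares the mean predicted value with the
#' observed proportion of breast-cancer deaths (Wilson 95% CI; a
#' Kaplan-Meier estimate of the same probability is available by flag).
#' Degenerate (e.g. constant) predictions collapse to fewer bins rather
#' than failing.
#'
#' @param cohort Patient data frame.
#' @param model A [pb_model()].
#' @param horizon Horizon in years (default 15).
#' @param n_bins Number of bins (default 5, i.e. quintiles).
#' @param observed `"proportion"` (default) or `"km"`.
#' @return Data frame with one row per bin: `bin`, `n`, `mean_predicted`,
#'   `observed`, `ci_lower`, `ci_upper`.
#' @export
quintile_calibration <- function(cohort, model, horizon = 15, n_bins = 5,
                                 observed = c("proportion", "km")) {
  observed <- match.arg(observed)
  pred <- predict_cumulative_mortality(cohort, model, t = horizon)$F_bc
  brk <- unique(stats::quantile(pred, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- if (length(brk) < 3) factor(rep(1, length(pred)))
          else cut(pred, breaks = brk, include.lowest = TRUE, labels = FALSE)
  ev <- cohort$died == 1L & as.character(cohort$cause) %in% "breast" &
    cohort$followup_time <= horizon
  rows <- lapply(sort(unique(bins)), function(b) {
    idx <- bins == b
    n <- sum(idx)
    if (observed == "proportion") {
      x <- sum(ev[idx])
      ci <- wilson_ci(x, n)
      obs <- x / n
    } else {
      sf <- survival::survfit(
        Surv(pmin(followup_time, horizon),
             as.integer(died == 1L & as.character(cause) %in% "breast" &
                          followup_time <= horizon)) ~ 1,
        data = cohort[idx, , drop = FALSE])
      s_t <- summary(sf, times = horizon, extend = TRUE)
      obs <- 1 - s_t$surv
      ci <- c(lower = 1 - s_t$upper, upper = 1 - s_t$lower)
    }
    data.frame(bin = b, n = n, mean_predicted = mean(pred[idx]),
               observed = obs, ci_lower = unname(ci["lower"]),
               ci_upper = unname(ci["upper"]))
  })
  do.call(rbind, rows)
}

## ------------------------------------------------------------------
## reclassification

#' Cross-classify predicted risks under two model versions
#'
#' Patients are classified into the clinical categories of predicted
#' breast-cancer-specific mortality at the horizon -- by default
#' `[0, 0.15)`, `[0.15, 0.20)` and `[0.20, 1]` (half-open, upper category
#' closed) -- under each model, and cross-tabulated.
#'
#' @param pred_old,pred_new Predicted mortality under the two versions
#'   (same patients, same order).
#' @param thresholds Two interior cut points (default `c(0.15, 0.20)`).
#' @return An object of class `reclass_matrix`: the 3x3 count matrix
#'   (rows = old model, columns = new model) with percentage matrix and the
#'   summary of [reclassification_summary()] attached.
#' @export
reclassify <- function(pred_old, pred_new, thresholds = c(0.15, 0.20)) {
  stopifnot(length(pred_old) == length(pred_new), length(thresholds) == 2)
  labs <- c(sprintf("[0,%.2f)", thresholds[1]),
            sprintf("[%.2f,%.2f)", thresholds[1], thresholds[2]),
            sprintf("[%.2f,1]", thresholds[2]))
  cls <- function(p) cut(p, breaks = c(0, thresholds, 1 + 1e-9),
                         right = FALSE, include.lowest = TRUE, labels = labs)
  counts <- table(old = cls(pred_old), new = cls(pred_new))
  counts <- unclass(counts)
  structure(
    list(counts = counts,
         percent = 100 * counts / sum(counts),
         summary = reclassification_summary(counts),
         thresholds = thresholds),
    class = "reclass_matrix"
  )
}

#' Summarise a reclassification matrix
#'
#' Works on a square matrix of counts or of percentages (rows = old
#' categories in increasing risk order, columns = new): percent of subjects
#' that changed category, moved up (above the diagonal) and moved down.
#'
#' @param m A square numeric matrix, or a `reclass_matrix`.
#' @return A list with `pct_changed`, `pct_up`, `pct_down`.
#' @export
reclassification_summary <- function(m) {
  if (inherits(m, "reclass_matrix")) m <- m$counts
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  tot <- sum(m)
  up <- sum(m[upper.tri(m)]); down <- sum(m[lower.tri(m)])
  list(pct_changed = 100 * (up + down) / tot,
       pct_up = 100 * up / tot,
       pct_down = 100 * down / tot)
}

#' @export
print.reclass_matrix <- function(x, ...) {
  cat("Reclassification (rows: old model, columns: new model)\n")
  print(x$counts)
  cat(sprintf("changed: %.1f%%  up: %.1f%%  down: %.1f%%\n",
              x$summary$pct_changed, x$summary$pct_up, x$summary$pct_down))
  invisible(x)
}
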