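## prognostic index and competing-risk absolute mortality

transform_fun <- function(name) {
  switch(name,
    identity = function(x) x,
    log      = function(x) log(x),
    log1p    = function(x) log1p(x),
    sqrt     = function(x) sqrt(x),
    square   = function(x) x^2,
    stop("unknown transform: ", name, call. = FALSE)
  )
}

## numeric screen-detection indicator: screen = 1, clinical = 0, a numeric
## propensity in [0, 1] passes through; missing contributes the clinical
## reference (run impute_detection_mode() first for mean imputation)
detection_screen_value <- function(cohort) {
  if ("detection_screen" %in% names(cohort))
    return(as.numeric(cohort$detection_screen))
  d <- as.character(cohort$detection)
  out <- suppressWarnings(as.numeric(d))
  out[d %in% "screen"] <- 1
  out[d %in% "clinical"] <- 0
  out[is.na(out)] <- 0
  out
}

eval_term <- function(term, cohort) {
  if (identical(term$type, "categorical")) {
    lev <- as.character(cohort[[term$predictor]])
    lev[is.na(lev)] <- "missing"
    known <- names(term$coefs)
    bad <- !lev %in% known
    if (any(bad))
      stop(sprintf("predictor '%s': level(s) %s not in model (rows %s)",
                   term$predictor, paste(unique(lev[bad]), collapse = ", "),
                   paste(utils::head(which(bad), 5), collapse = ", ")),
           call. = FALSE)
    unlist(term$coefs)[lev]
  } else {
    x <- if (term$predictor == "detection_screen") detection_screen_value(cohort)
         else as.numeric(cohort[[term$predictor]])
    if (anyNA(x))
      stop(sprintf("predictor '%s' is missing for rows %s", term$predictor,
                   paste(utils::head(which(is.na(x)), 5), collapse = ", ")),
           call. = FALSE)
    term$coef * (transform_fun(term$transform)(x) - term$ref) / term$scale
  }
}

check_mandatory <- function(cohort) {
  for (v in c("age", "tumour_size", "grade", "positive_nodes", "er")) {
    if (is.null(cohort[[v]]))
      stop("mandatory covariate absent: ", v, call. = FALSE)
    if (anyNA(cohort[[v]]))
      stop(sprintf("mandatory covariate '%s' missing for rows %s", v,
                   paste(utils::head(which(is.na(cohort[[v]])), 5),
                         collapse = ", ")), call. = FALSE)
  }
  invisible(cohort)
}

stratum_of <- function(er) {
  er <- as.character(er)
  bad <- !er %in% c("negative", "positive")
  if (any(bad))
    stop("er must be 'negative' or 'positive'; offending values: ",
         paste(unique(er[bad]), collapse = ", "), call. = FALSE)
  ifelse(er == "positive", "ER-positive", "ER-negative")
}

#' Prognostic index (log relative hazard) for each patient
#'
#' The prognostic index is the sum of the stratum's coefficient terms
#' evaluated at the patient's covariates plus, for the breast cause, the log
#' of the rescaled hazard ratio matching the patient's level of each attached
#' biomarker (missing status contributes `log(1) = 0`).  The stratum is
#' chosen per patient from the `er` column.
#'
#' @param cohort Data frame of patient records (see [read_cohort()] for the
#'   column schema).
#' @param model A [pb_model()].
#' @param cause `"breast"` or `"other"`.
#' @return Numeric vector, one log relative hazard per row.
#' @export
prognostic_index <- function(cohort, model, cause = c("breast", "other")) {
  cause <- match.arg(cause)
  stopifnot(inherits(model, "pb_model"))
  check_mandatory(cohort)
  strat <- stratum_of(cohort$er)
  pi_out <- numeric(nrow(cohort))
  for (s in unique(strat)) {
    idx <- which(strat == s)
    part <- model$strata[[s]][[cause]]
    sub <- cohort[idx, , drop = FALSE]
    contrib <- rowSums(do.call(cbind, c(
      lapply(part$terms, eval_term, cohort = sub),
      list(rep(0, nrow(sub)))
    )))
    for (bm in part$biomarkers) {
      col <- tolower(bm$name)
      level <- if (is.null(sub[[col]])) rep("missing", nrow(sub)) else sub[[col]]
      contrib <- contrib + biomarker_log_hr(bm, level)
    }
    pi_out[idx] <- contrib
  }
  pi_out
}

#' Treatment relative hazard on breast-cancer-specific mortality
#'
#' Multiplies the relative hazards of the treatments recorded for each
#' patient: chemotherapy by regimen (`chemo` one of `"none"`,
#' `"anthracycline"`, `"taxane"`), hormone therapy (applied only in
#' ER-positive disease) and trastuzumab.  Absent treatment multiplies by 1.
#' A bare `"yes"` chemotherapy flag without a regimen is an error; run
#' [assign_nz_treatments()] first for registry-style cohorts.
#'
#' @param cohort Patient data frame.
#' @param model A [pb_model()] supplying the relative hazards.
#' @return Numeric vector of hazard multipliers.
#' @export
treatment_rh <- function(cohort, model) {
  n <- nrow(cohort)
  rx <- rep(1, n)
  chemo <- as.character(cohort$chemo %||% rep("none", n))
  chemo[is.na(chemo)] <- "none"
  if (any(chemo == "yes"))
    stop("chemo regimen unresolved ('yes'); run assign_nz_treatments() first",
         call. = FALSE)
  regimens <- names(model$treatments$chemotherapy)
  bad <- !chemo %in% c("none", regimens)
  if (any(bad))
    stop("unknown chemotherapy regimen: ",
         paste(unique(chemo[bad]), collapse = ", "), call. = FALSE)
  on_chemo <- chemo != "none"
  rx[on_chemo] <- rx[on_chemo] * model$treatments$chemotherapy[chemo[on_chemo]]
  hormone <- as_flag(cohort$hormone %||% rep(FALSE, n))
  er_pos <- as.character(cohort$er) == "positive"
  rx[hormone & er_pos] <- rx[hormone & er_pos] * model$treatments$hormone
  tras <- as_flag(cohort$trastuzumab %||% rep(FALSE, n))
  rx[tras] <- rx[tras] * model$treatments$trastuzumab
  rx
}

as_flag <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- tolower(as.character(x))
  !is.na(x) & x %in% c("1", "yes", "true", "y")
}

## cumulative baseline hazard at arbitrary t in [0, 15]: linear interpolation
## of the yearly grid (piecewise-constant hazard within each year)
baseline_at <- function(h0, t) {
  stats::approx(0:15, h0, xout = pmin(pmax(t, 0), 15), rule = 2)$y
}

#' Predict cumulative cause-specific and all-cause mortality
#'
#' The engine works on a yearly grid: within each year the adjusted
#' cause-specific cumulative-hazard increments are
#' `dH_bc = dH0_bc * exp(PI_bc) * rx` (treatments multiply the breast-cause
#' hazard) and `dH_oth = dH0_oth * exp(PI_oth)`; deaths in the year,
#' `S(j-1) * (1 - exp(-(dH_bc + dH_oth)))`, are attributed to each cause in
#' proportion to its increment.  All-cause mortality is the exact sum of the
#' two components.  A fractional final year uses the interpolated baseline.
#'
#' @param cohort Patient data frame.
#' @param model A [pb_model()].
#' @param t Horizon(s) in years since diagnosis: either a single value, a
#'   vector of horizons applied to every patient, or (with
#'   `per_patient = TRUE`) one horizon per row.  All in `[0, 15]`.
#' @param per_patient If `TRUE`, `t` has one entry per patient and the result
#'   has one row per patient.
#' @return A data frame with columns `id`, `t`, `F_bc`, `F_oth`, `F_all`
#'   (cumulative breast-specific, other-cause and all-cause mortality, all in
#'   `[0, 1]`), one row per patient per horizon.
#' @export
predict_cumulative_mortality <- function(cohort, model, t = 15,
                                         per_patient = FALSE) {
  stopifnot(inherits(model, "pb_model"))
  if (any(!is.finite(t)) || any(t < 0) || any(t > 15))
    stop("horizon t must lie in [0, 15]", call. = FALSE)
  n <- nrow(cohort)
  if (per_patient && length(t) != n)
    stop("per_patient = TRUE requires one horizon per row", call. = FALSE)

  pi_bc <- prognostic_index(cohort, model, "breast")
  pi_oth <- prognostic_index(cohort, model, "other")
  rx <- treatment_rh(cohort, model)
  strat <- stratum_of(cohort$er)
  ids <- cohort$id %||% seq_len(n)

  one_horizon <- function(tt) {
    ## tt: vector of horizons, length n
    F_bc <- F_oth <- numeric(n)
    S <- rep(1, n)
    for (j in 1:15) {
      up <- pmin(tt, j)
      lo <- pmin(tt, j - 1)
      d_bc <- d_oth <- numeric(n)
      for (s in unique(strat)) {
        idx <- strat == s
        d_bc[idx] <- (baseline_at(model$baseline[[s]]$breast, up[idx]) -
                      baseline_at(model$baseline[[s]]$breast, lo[idx])) *
                     exp(pi_bc[idx]) * rx[idx]
        d_oth[idx] <- (baseline_at(model$baseline[[s]]$other, up[idx]) -
                       baseline_at(model$baseline[[s]]$other, lo[idx])) *
                      exp(pi_oth[idx])
      }
      d_tot <- d_bc + d_oth
      dead <- S * (1 - exp(-d_tot))
      frac <- ifelse(d_tot > 0, d_bc / d_tot, 0)
      F_bc <- F_bc + dead * frac
      F_oth <- F_oth + dead * (1 - frac)
      S <- S * exp(-d_tot)
    }
    data.frame(id = ids, t = tt, F_bc = F_bc, F_oth = F_oth,
               F_all = F_bc + F_oth)
  }

  if (per_patient) return(one_horizon(as.numeric(t)))
  out <- lapply(t, function(tt) one_horizon(rep(tt, n)))
  do.call(rbind, out)
}

#' Write predictions as delimited text
#'
#' One row per patient per horizon, CSV.
#'
#' @param predictions Output of [predict_cumulative_mortality()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
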