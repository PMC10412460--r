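## cohort data model, IO, eligibility, imputation, follow-up conventions

cohort_required_cols <- c(
  "id", "study_id", "diagnosis_year", "age", "tumour_size", "grade",
  "positive_nodes", "er", "pr", "her2", "detection", "chemo", "hormone",
  "trastuzumab", "entry_time", "followup_time", "died", "cause"
)
cohort_optional_cols <- c(
  "ki67", "ethnicity", "metastatic", "primary_surgery", "detection_screen"
)

#' Read a patient cohort from delimited text
#'
#' Expects a CSV with one row per patient and the fixed column schema
#' (header names): `r paste(cohort_required_cols, collapse = ", ")`, plus
#' optional `r paste(cohort_optional_cols, collapse = ", ")`.  Unknown
#' columns are ignored with a warning.  Status columns use
#' `negative`/`positive`/`missing`; `detection` uses
#' `clinical`/`screen`/`missing` (or a numeric screen propensity after
#' imputation); `cause` uses `breast`/`other`/`unknown` and must be present
#' only for deaths.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_required_cols, names(df))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(df), c(cohort_required_cols, cohort_optional_cols))
  if (length(unknown)) {
    warning("ignoring unknown cohort column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    df <- df[setdiff(names(df), unknown)]
  }
  for (v in c("diagnosis_year", "age", "tumour_size", "positive_nodes",
              "entry_time", "followup_time"))
    df[[v]] <- as.numeric(df[[v]])
  df$died <- as.integer(df$died)
  validate_cohort(df)
  df
}

#' Write a cohort as delimited text
#' @param cohort Data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_cohort <- function(cohort) {
  bad_grade <- !as.character(cohort$grade) %in% c("1", "2", "3")
  if (any(bad_grade))
    stop("unparseable grade for row id(s): ",
         paste(utils::head(cohort$id[bad_grade], 5), collapse = ", "),
         call. = FALSE)
  for (v in c("er", "pr", "her2")) {
    ok <- c("negative", "positive", if (v != "er") "missing")
    bad <- !as.character(cohort[[v]]) %in% ok & !is.na(cohort[[v]])
    if (any(bad))
      stop(sprintf("unparseable %s status for row id(s): %s", v,
                   paste(utils::head(cohort$id[bad], 5), collapse = ", ")),
           call. = FALSE)
  }
  neg_fu <- !is.na(cohort$followup_time) & !is.na(cohort$entry_time) &
    (cohort$entry_time < 0 | cohort$followup_time < cohort$entry_time)
  if (any(neg_fu))
    warning("follow-up precedes entry for ", sum(neg_fu),
            " row(s); they will fail eligibility", call. = FALSE)
  invisible(cohort)
}

#' Apply eligibility rules and tally exclusions
#'
#' Rules are applied sequentially in a fixed order so tallies are
#' reproducible; a record failing several rules is counted once, at the
#' first.  Common rules: age at diagnosis under 25 or over 85, tumour
#' diameter over 20 cm, more than 20 positive nodes.  The estimation flavour
#' additionally drops diagnoses outside `year_range` and records with
#' incomplete core factors (size, grade, nodes, ER, PR).  The validation
#' flavour drops metastatic disease at diagnosis, records without primary
#' surgery, and inconsistent follow-up (negative times or follow-up before
#' entry).
#'
#' @param cohort Data frame.
#' @param type `"estimation"` or `"validation"`.
#' @param year_range Diagnosis-year window for the estimation flavour.
#' @return A list of class `eligibility_result` with `cohort` (the survivors,
#'   original order) and `exclusions` (named integer tally per rule, in
#'   application order).
#' @export
apply_eligibility <- function(cohort, type = c("estimation", "validation"),
                              year_range = c(1990, 2017)) {
  type <- match.arg(type)
  rules <- list(
    age = function(d) d$age < 25 | d$age > 85,
    tumour_size = function(d) d$tumour_size > 20,
    positive_nodes = function(d) d$positive_nodes > 20
  )
  if (type == "estimation") {
    rules$diagnosis_year <- function(d)
      d$diagnosis_year < year_range[1] | d$diagnosis_year > year_range[2]
    rules$incomplete_core <- function(d)
      is.na(d$tumour_size) | is.na(d$grade) | is.na(d$positive_nodes) |
        is.na(d$er) | is.na(d$pr) | d$pr %in% "missing"
  } else {
    rules$metastatic <- function(d) as_flag(d$metastatic %||% rep(FALSE, nrow(d)))
    rules$no_primary_surgery <- function(d)
      !as_flag(d$primary_surgery %||% rep(TRUE, nrow(d)))
    rules$inconsistent_followup <- function(d)
      is.na(d$followup_time) | is.na(d$entry_time) | d$entry_time < 0 |
        d$followup_time < d$entry_time
  }
  keep <- rep(TRUE, nrow(cohort))
  tally <- stats::setNames(integer(length(rules)), names(rules))
  for (r in names(rules)) {
    hit <- keep & isTRUE_vec(rules[[r]](cohort))
    tally[r] <- sum(hit)
    keep <- keep & !hit
  }
  structure(list(cohort = cohort[keep, , drop = FALSE], exclusions = tally),
            class = "eligibility_result")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.eligibility_result <- function(x, ...) {
  cat(sprintf("Eligible: %d rows; excluded %d\n",
              nrow(x$cohort), sum(x$exclusions)))
  for (r in names(x$exclusions))
    cat(sprintf("  %-22s %d\n", r, x$exclusions[r]))
  invisible(x)
}

#' Impute missing mode of detection
#'
#' Patients with missing detection mode aged under 50 or over 70 at diagnosis
#' are assumed clinically detected; for the remaining missing values (ages
#' 50--70) mean imputation is used: the screen-propensity is set to the mean
#' of the screen indicator among complete cases aged 50--70.  Non-missing
#' values are never altered.  The result carries a numeric
#' `detection_screen` column (0 = clinical, 1 = screen, fraction = imputed)
#' used by the prognostic index.
#'
#' @param cohort Data frame with a `detection` column
#'   (`clinical`/`screen`/`missing`/`NA`).
#' @return The cohort with `detection_screen` filled in.
#' @export
impute_detection_mode <- function(cohort) {
  d <- as.character(cohort$detection)
  d[is.na(d)] <- "missing"
  bad <- !d %in% c("clinical", "screen", "missing")
  if (any(bad))
    stop("unparseable detection mode for row id(s): ",
         paste(utils::head(cohort$id[bad], 5), collapse = ", "), call. = FALSE)
  screen <- ifelse(d == "screen", 1, ifelse(d == "clinical", 0, NA_real_))
  if ("detection_screen" %in% names(cohort)) {
    keep <- !is.na(cohort$detection_screen)
    screen[keep] <- cohort$detection_screen[keep]
  }
  miss <- is.na(screen)
  young_old <- cohort$age < 50 | cohort$age > 70
  screen[miss & young_old] <- 0
  d[miss & young_old] <- "clinical"
  mid <- !is.na(cohort$age) & cohort$age >= 50 & cohort$age <= 70
  still <- is.na(screen)
  if (any(still)) {
    complete_mid <- mid & !is.na(screen)
    if (!any(complete_mid))
      stop("cannot mean-impute detection: no complete cases aged 50-70",
           call. = FALSE)
    screen[still] <- mean(screen[complete_mid])
  }
  cohort$detection <- d
  cohort$detection_screen <- screen
  cohort
}

#' Resolve registry treatment flags into model treatment assignments
#'
#' Population registries often record only whether chemotherapy was given,
#' not the regimen, and may not record trastuzumab at all.  The `primary`
#' policy assumes an anthracycline-based regimen for chemotherapy in patients
#' diagnosed before `year_cut` and a taxane-based regimen from `year_cut`
#' onward, and assumes trastuzumab for HER2-positive patients diagnosed
#' after `year_cut`.  Sensitivity policies: `all_anthracycline` makes every
#' chemotherapy anthracycline-based (trastuzumab as primary);
#' `all_her2_trastuzumab` gives every HER2-positive patient trastuzumab,
#' with the period-based regimen.
#'
#' @param cohort Data frame with `chemo` flags (`yes`/`no`/regimen labels),
#'   `her2` and `diagnosis_year`.
#' @param policy One of `"primary"`, `"all_anthracycline"`,
#'   `"all_her2_trastuzumab"`.
#' @param year_cut Calendar-year cut point (default 2010).
#' @return The cohort with `chemo` resolved to
#'   `none`/`anthracycline`/`taxane` and a logical `trastuzumab` column.
#' @export
assign_nz_treatments <- function(cohort,
                                 policy = c("primary", "all_anthracycline",
                                            "all_her2_trastuzumab"),
                                 year_cut = 2010) {
  policy <- match.arg(policy)
  chemo <- tolower(as.character(cohort$chemo))
  chemo[is.na(chemo) | chemo %in% c("no", "none", "0", "false")] <- "none"
  on_chemo <- chemo != "none"
  regimen <- ifelse(cohort$diagnosis_year < year_cut, "anthracycline", "taxane")
  if (policy == "all_anthracycline") regimen[] <- "anthracycline"
  chemo[on_chemo] <- regimen[on_chemo]
  her2_pos <- as.character(cohort$her2) %in% "positive"
  tras <- if (policy == "all_her2_trastuzumab") her2_pos
          else her2_pos & cohort$diagnosis_year > year_cut
  cohort$chemo <- chemo
  cohort$trastuzumab <- tras
  cohort
}

#' Follow-up windows for validation
#'
#' Adds the analysis quantities used by the validation suite:
#' `analysis_time` (follow-up capped at `horizon`), `event_breast` (death
#' from breast cancer within the window), `potential_followup` (for deaths:
#' diagnosis to the administrative censor date, capped at `horizon`) and
#' `expected_horizon` -- the per-patient horizon at which expected mortality
#' is evaluated: observed follow-up for survivors, potential follow-up for
#' deaths.
#'
#' @param cohort Data frame.
#' @param censor_date Administrative censor date as a decimal year
#'   (default 2014-12-31).
#' @param horizon Maximum horizon in years (default 15).
#' @return The cohort with the four columns added.
#' @export
followup_window <- function(cohort, censor_date = decimal_year("2014-12-31"),
                            horizon = 15) {
  if (anyNA(cohort$followup_time))
    stop("missing follow-up time for row id(s): ",
         paste(utils::head(cohort$id[is.na(cohort$followup_time)], 5),
               collapse = ", "), call. = FALSE)
  cohort$analysis_time <- pmin(cohort$followup_time, horizon)
  cohort$event_breast <- as.integer(
    cohort$died == 1L & as.character(cohort$cause) %in% "breast" &
      cohort$followup_time <= horizon
  )
  potential <- pmin(pmax(censor_date - cohort$diagnosis_year, 0), horizon)
  died <- cohort$died == 1L
  ## deaths recorded after the censor date keep their (capped) follow-up
  cohort$potential_followup <- ifelse(died, pmax(potential, cohort$analysis_time),
                                      cohort$analysis_time)
  cohort$expected_horizon <- ifelse(died, cohort$potential_followup,
                                    cohort$analysis_time)
  cohort
}

#' Convert a calendar date to a decimal year
#' @param date A `Date` or `"YYYY-MM-DD"` string.
#' @return Decimal year (e.g. mid-2000 is about 2000.5).
#' @export
decimal_year <- function(date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  start <- as.Date(sprintf("%d-01-01", yr))
  end <- as.Date(sprintf("%d-01-01", yr + 1L))
  yr + as.numeric(date - start) / as.numeric(end - start)
}
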