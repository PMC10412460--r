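#' Rescale a binary biomarker hazard ratio to a population-average of unity
#'
#' An absolute-risk model whose baseline hazard was estimated in a cohort with
#' unknown biomarker status implicitly describes a patient with *average*
#' status.  To attach a new binary biomarker to such a model without touching
#' the baseline, its externally estimated hazard ratio (positive versus
#' negative) is re-expressed as a pair of per-level hazard ratios whose
#' prevalence-weighted arithmetic mean is exactly one:
#'
#' \deqn{HR_{neg} = \frac{1}{p\,HR + (1-p)}, \qquad
#'       HR_{pos} = \frac{HR}{p\,HR + (1-p)}}
#'
#' where `p` is the prevalence of biomarker positivity in the target
#' population.  A patient with missing status keeps the population average,
#' i.e. a multiplier of one.
#'
#' The arithmetic-mean convention (not a geometric/log-scale mean) is used
#' throughout: the reference level of the rescaled pair is a hypothetical
#' patient with average biomarker status on the hazard-ratio scale.
#'
#' @param hr_pos_vs_neg Hazard ratio for biomarker-positive versus
#'   biomarker-negative tumours (strictly positive).
#' @param prevalence_pos Prevalence of biomarker positivity in the population
#'   the baseline hazard describes; strictly inside (0, 1).
#' @param name Biomarker label, e.g. `"PR"`, `"HER2"`, `"KI67"`.
#'
#' @return An object of class `biomarker_term`: a list with elements `name`,
#'   `hr_pos_vs_neg`, `prevalence_pos`, `rescaled_hr_neg`, `rescaled_hr_pos`
#'   and `rescaled_hr_missing` (always 1).  Internal values are unrounded;
#'   printing rounds to two decimals (half-even).
#'
#' @examples
#' # progesterone receptor in ER-negative disease
#' rescale_binary_biomarker(0.77, 0.14, name = "PR")
#'
#' @export
rescale_binary_biomarker <- function(hr_pos_vs_neg, prevalence_pos, name = "PR") {
  if (!is.numeric(hr_pos_vs_neg) || length(hr_pos_vs_neg) != 1L ||
      !is.finite(hr_pos_vs_neg) || hr_pos_vs_neg <= 0)
    stop("`hr_pos_vs_neg` must be a single positive number", call. = FALSE)
  if (!is.numeric(prevalence_pos) || length(prevalence_pos) != 1L ||
      !is.finite(prevalence_pos) || prevalence_pos <= 0 || prevalence_pos >= 1)
    stop("`prevalence_pos` must lie strictly inside (0, 1)", call. = FALSE)

  denom <- prevalence_pos * hr_pos_vs_neg + (1 - prevalence_pos)
  structure(
    list(
      name                = name,
      hr_pos_vs_neg       = hr_pos_vs_neg,
      prevalence_pos      = prevalence_pos,
      rescaled_hr_neg     = 1 / denom,
      rescaled_hr_pos     = hr_pos_vs_neg / denom,
      rescaled_hr_missing = 1
    ),
    class = "biomarker_term"
  )
}

#' @export
print.biomarker_term <- function(x, ...) {
  cat(sprintf("Biomarker term: %s\n", x$name))
  cat(sprintf("  raw HR (pos vs neg): %.2f   prevalence positive: %.0f%%\n",
              x$hr_pos_vs_neg, 100 * x$prevalence_pos))
  cat(sprintf("  rescaled HR  negative: %.2f  positive: %.2f  missing: %.2f\n",
              x$rescaled_hr_neg, x$rescaled_hr_pos, x$rescaled_hr_missing))
  invisible(x)
}

#' Log hazard-ratio contribution of a biomarker term for a given status
#'
#' @param term A [rescale_binary_biomarker()] object.
#' @param level Character vector of statuses: `"negative"`, `"positive"` or
#'   `"missing"` (`NA` is treated as missing).
#' @return Numeric vector of log rescaled hazard ratios; missing status
#'   contributes `log(1) = 0`.
#' @export
biomarker_log_hr <- function(term, level) {
  stopifnot(inherits(term, "biomarker_term"))
  level <- as.character(level)
  level[is.na(level)] <- "missing"
  bad <- !level %in% c("negative", "positive", "missing")
  if (any(bad))
    stop("unknown biomarker status: ", paste(unique(level[bad]), collapse = ", "),
         call. = FALSE)
  out <- numeric(length(level))
  out[level == "negative"] <- log(term$rescaled_hr_neg)
  out[level == "positive"] <- log(term$rescaled_hr_pos)
  out
}

#' Progesterone-receptor terms for the ER-stratified model
#'
#' Convenience constructor for the pair of PR terms used when upgrading the
#' ER-stratified model: the offset-adjusted hazard ratios (PR-positive versus
#' PR-negative) and the PR-positivity prevalences default to the consortium
#' estimates of 0.77 at 14% positivity for ER-negative disease and 0.72 at
#' 83% for ER-positive disease.
#'
#' @param hr_er_neg,hr_er_pos Offset-adjusted hazard ratios per ER stratum.
#' @param prev_er_neg,prev_er_pos PR-positivity prevalence per ER stratum.
#' @return Named list of two `biomarker_term` objects
#'   (`"ER-negative"`, `"ER-positive"`).
#' @export
pr_biomarker_terms <- function(hr_er_neg = 0.77, prev_er_neg = 0.14,
                               hr_er_pos = 0.72, prev_er_pos = 0.83) {
  list(
    "ER-negative" = rescale_binary_biomarker(hr_er_neg, prev_er_neg, name = "PR"),
    "ER-positive" = rescale_binary_biomarker(hr_er_pos, prev_er_pos, name = "PR")
  )
}
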