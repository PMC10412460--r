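#' @title ER-stratified absolute-risk model parameters
#'
#' @description A `pb_model` bundles everything needed to turn a patient
#' record into cumulative cause-specific mortality: per-ER-stratum coefficient
#' sets for breast-cancer-specific and other-cause mortality, per-stratum
#' baseline cumulative hazards on a yearly grid over 0--15 years, treatment
#' relative hazards, and per-stratum biomarker terms (rescaled to a
#' population-average hazard ratio of one, see
#' [rescale_binary_biomarker()]).
#'
#' Coefficient terms are either continuous,
#' `list(predictor=, type="continuous", transform=, ref=, scale=, coef=)`
#' with contribution `coef * (g(x) - ref) / scale`, or categorical,
#' `list(predictor=, type="categorical", coefs=list(level=value, ...))`.
#'
#' @param version Model version label, e.g. `"2.2"`.
#' @param strata Named list (`"ER-negative"`, `"ER-positive"`), each with
#'   elements `breast` and `other`, each of those a list with `terms` (list of
#'   term specs) and `biomarkers` (list of `biomarker_term`).
#' @param baseline Named list per stratum, each with numeric vectors `breast`
#'   and `other` of length 16: the cumulative baseline hazard at years 0..15
#'   (`H0(0) = 0`, non-decreasing, finite).
#' @param treatments List with `chemotherapy` (named vector of relative
#'   hazards by regimen, e.g. anthracycline, taxane), `hormone` and
#'   `trastuzumab` (scalars).  All strictly positive; an absent treatment
#'   always multiplies by 1.
#' @return An object of class `pb_model`.
#' @export
pb_model <- function(version, strata, baseline, treatments) {
  m <- structure(
    list(version = as.character(version), strata = strata,
         baseline = baseline, treatments = treatments),
    class = "pb_model"
  )
  validate_pb_model(m)
  m
}

model_strata <- c("ER-negative", "ER-positive")
model_causes <- c("breast", "other")

validate_pb_model <- function(m) {
  stopifnot(inherits(m, "pb_model"))
  if (!all(model_strata %in% names(m$strata)))
    stop("model must define strata ", paste(model_strata, collapse = ", "),
         call. = FALSE)
  for (s in model_strata) {
    for (cause in model_causes) {
      part <- m$strata[[s]][[cause]]
      if (is.null(part$terms))
        stop(sprintf("stratum %s, cause %s: missing terms", s, cause),
             call. = FALSE)
      for (bm in part$biomarkers)
        if (!inherits(bm, "biomarker_term"))
          stop("biomarkers must be biomarker_term objects", call. = FALSE)
      h0 <- m$baseline[[s]][[cause]]
      if (length(h0) != 16L || any(!is.finite(h0)))
        stop(sprintf("baseline %s/%s must be 16 finite values (years 0..15)",
                     s, cause), call. = FALSE)
      if (h0[1] != 0 || any(diff(h0) < 0))
        stop(sprintf("baseline %s/%s must start at 0 and be non-decreasing",
                     s, cause), call. = FALSE)
    }
  }
  trh <- c(unlist(m$treatments$chemotherapy), m$treatments$hormone,
           m$treatments$trastuzumab)
  if (any(!is.finite(trh)) || any(trh <= 0))
    stop("treatment relative hazards must be strictly positive", call. = FALSE)
  invisible(m)
}

#' @export
print.pb_model <- function(x, ...) {
  cat(sprintf("ER-stratified absolute-risk model, version %s\n", x$version))
  for (s in model_strata) {
    bms <- vapply(x$strata[[s]]$breast$biomarkers, `[[`, "", "name")
    cat(sprintf("  %s: %d breast terms, %d other-cause terms, biomarkers: %s\n",
                s, length(x$strata[[s]]$breast$terms),
                length(x$strata[[s]]$other$terms),
                if (length(bms)) paste(bms, collapse = ", ") else "none"))
  }
  cat(sprintf("  treatments: chemo [%s], hormone %.2f, trastuzumab %.2f\n",
              paste(sprintf("%s %.2f", names(x$treatments$chemotherapy),
                            x$treatments$chemotherapy), collapse = ", "),
              x$treatments$hormone, x$treatments$trastuzumab))
  invisible(x)
}

#' Incorporate a rescaled biomarker term into a model
#'
#' Returns a new model whose only difference from the input is the extra
#' biomarker term in the breast-cancer coefficient set of the requested
#' stratum (and the version label, if supplied): every other coefficient and
#' both baseline hazards are carried over unchanged, which is the point of
#' the mean-unity rescaling.
#'
#' @param model A [pb_model()].
#' @param term A [rescale_binary_biomarker()] object, or a named list of them
#'   keyed by stratum (as produced by [pr_biomarker_terms()]).
#' @param stratum Stratum to receive the term when `term` is a single object;
#'   ignored when `term` is a per-stratum list.
#' @param version Optional new version label (e.g. `"2.3"`); default keeps
#'   the old label.
#' @return A new `pb_model`.
#' @export
incorporate_biomarker <- function(model, term, stratum = NULL, version = NULL) {
  stopifnot(inherits(model, "pb_model"))
  if (inherits(term, "biomarker_term")) {
    if (is.null(stratum))
      stop("`stratum` is required for a single biomarker term", call. = FALSE)
    term <- stats::setNames(list(term), stratum)
  }
  out <- model
  for (s in names(term)) {
    if (!s %in% model_strata) stop("unknown stratum: ", s, call. = FALSE)
    tm <- term[[s]]
    stopifnot(inherits(tm, "biomarker_term"))
    existing <- vapply(out$strata[[s]]$breast$biomarkers, `[[`, "", "name")
    if (tm$name %in% existing)
      stop(sprintf("biomarker '%s' already present in stratum %s",
                   tm$name, s), call. = FALSE)
    out$strata[[s]]$breast$biomarkers <-
      c(out$strata[[s]]$breast$biomarkers, list(tm))
  }
  if (!is.null(version)) out$version <- as.character(version)
  validate_pb_model(out)
  out
}

#' Remove a biomarker term from a model
#'
#' @param model A [pb_model()].
#' @param name Biomarker name to drop.
#' @param stratum Strata to drop it from (default: both).
#' @param version Optional new version label.
#' @return A new `pb_model` without the named term.
#' @export
remove_biomarker <- function(model, name, stratum = model_strata,
                             version = NULL) {
  stopifnot(inherits(model, "pb_model"))
  out <- model
  for (s in stratum) {
    bms <- out$strata[[s]]$breast$biomarkers
    keep <- vapply(bms, function(b) b$name != name, TRUE)
    out$strata[[s]]$breast$biomarkers <- bms[keep]
  }
  if (!is.null(version)) out$version <- as.character(version)
  out
}

## ------------------------------------------------------------------
## configuration file IO (YAML key-value tree)

term_to_list <- function(tm) tm[!vapply(tm, is.null, TRUE)]

#' Read model parameters from a YAML configuration file
#'
#' The configuration is a key-value tree with `model_version`, `treatments`,
#' per-stratum `strata` (coefficient terms and raw biomarker entries of the
#' form `{name, hr, prevalence}` which are rescaled on load) and per-stratum
#' `baseline` cumulative-hazard vectors at years 0..15.  Schema problems are
#' reported as errors, not silently patched.
#'
#' @param path Path to a YAML file.
#' @return A [pb_model()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (key in c("model_version", "strata", "baseline", "treatments"))
    if (is.null(cfg[[key]]))
      stop("config missing required key: ", key, call. = FALSE)
  strata <- lapply(cfg$strata, function(sc) {
    lapply(sc, function(part) {
      list(
        terms = lapply(part$terms, function(tm) {
          if (identical(tm$type, "categorical")) {
            list(predictor = tm$predictor, type = "categorical",
                 coefs = lapply(tm$coefs, as.numeric))
          } else {
            list(predictor = tm$predictor, type = "continuous",
                 transform = tm$transform %||% "identity",
                 ref = as.numeric(tm$ref %||% 0),
                 scale = as.numeric(tm$scale %||% 1),
                 coef = as.numeric(tm$coef))
          }
        }),
        biomarkers = lapply(part$biomarkers, function(b)
          rescale_binary_biomarker(as.numeric(b$hr), as.numeric(b$prevalence),
                                   name = b$name))
      )
    })
  })
  baseline <- lapply(cfg$baseline, function(b) lapply(b, as.numeric))
  treatments <- list(
    chemotherapy = unlist(cfg$treatments$chemotherapy),
    hormone = as.numeric(cfg$treatments$hormone),
    trastuzumab = as.numeric(cfg$treatments$trastuzumab)
  )
  pb_model(cfg$model_version, strata, baseline, treatments)
}

#' Write model parameters to a YAML configuration file
#'
#' Inverse of [read_model_config()]; biomarker terms are stored as their raw
#' hazard ratio and prevalence and re-derived on load, so a write/read round
#' trip reproduces the model.
#'
#' @param model A [pb_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "pb_model"))
  cfg <- list(
    model_version = model$version,
    treatments = list(
      chemotherapy = as.list(model$treatments$chemotherapy),
      hormone = model$treatments$hormone,
      trastuzumab = model$treatments$trastuzumab
    ),
    strata = lapply(model$strata, function(sc) {
      lapply(sc, function(part) {
        list(
          terms = lapply(part$terms, term_to_list),
          biomarkers = lapply(part$biomarkers, function(b)
            list(name = b$name, hr = b$hr_pos_vs_neg,
                 prevalence = b$prevalence_pos))
        )
      })
    }),
    baseline = model$baseline
  )
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
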