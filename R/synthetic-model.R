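#' A synthetic baseline model configuration
#'
#' Builds a complete, internally consistent `pb_model` labelled version
#' `"2.2"` whose coefficients, baseline hazards and treatment effects are
#' **synthetic**: they are plausible for early invasive breast cancer (risk
#' increasing with age, size, node count and grade; screen detection
#' protective; HER2 and KI67 attached as rescaled biomarker terms) but are
#' not the published tool's values, which are consumed as configuration and
#' are deliberately not shipped.  The fixture exists so that every stage --
#' prognostic index, competing-risk prediction, offset estimation,
#' validation -- can be exercised end to end with known ground truth.
#'
#' The same model is available as a YAML file at
#' `system.file("extdata", "model_synthetic_v22.yaml", package = "prbreast")`.
#'
#' @return A [pb_model()] labelled `"2.2"`.
#' @export
synthetic_model_v22 <- function() {
  cont <- function(predictor, transform, ref, scale, coef)
    list(predictor = predictor, type = "continuous", transform = transform,
         ref = ref, scale = scale, coef = coef)
  cat_ <- function(predictor, coefs)
    list(predictor = predictor, type = "categorical", coefs = coefs)

  breast_neg <- list(
    terms = list(
      cont("age", "identity", 57, 10, 0.12),
      cont("tumour_size", "sqrt", 1.449, 1, 0.70),
      cont("positive_nodes", "log1p", 0.788, 1, 0.50),
      cat_("grade", list("1" = -0.70, "2" = 0, "3" = 0.25)),
      cont("detection_screen", "identity", 0.10, 1, -0.40)
    ),
    biomarkers = list(rescale_binary_biomarker(1.25, 0.16, name = "HER2"))
  )
  breast_pos <- list(
    terms = list(
      cont("age", "identity", 57, 10, 0.30),
      cont("tumour_size", "sqrt", 1.449, 1, 0.75),
      cont("positive_nodes", "log1p", 0.788, 1, 0.55),
      cat_("grade", list("1" = -0.85, "2" = 0, "3" = 0.45)),
      cont("detection_screen", "identity", 0.25, 1, -0.55)
    ),
    biomarkers = list(
      rescale_binary_biomarker(1.30, 0.16, name = "HER2"),
      rescale_binary_biomarker(1.30, 0.55, name = "KI67")
    )
  )
  other_terms <- list(terms = list(cont("age", "identity", 57, 10, 0.90)),
                      biomarkers = list())

  h_bc_neg <- 2.0 * cumsum(c(0, 0.022, 0.028, 0.027, 0.022, 0.017, 0.013,
                             0.010, 0.008, 0.007, 0.006, 0.005, 0.005, 0.004,
                             0.004, 0.004))
  h_bc_pos <- 2.0 * cumsum(c(0, 0.004, 0.007, 0.009, 0.010, 0.011, 0.011,
                             0.011, 0.010, 0.010, 0.009, 0.009, 0.008, 0.008,
                             0.008, 0.007))
  h_oth <- cumsum(c(0, 0.0033 * 1.06^(0:14)))

  pb_model(
    version = "2.2",
    strata = list(
      "ER-negative" = list(breast = breast_neg, other = other_terms),
      "ER-positive" = list(breast = breast_pos, other = other_terms)
    ),
    baseline = list(
      "ER-negative" = list(breast = h_bc_neg, other = h_oth),
      "ER-positive" = list(breast = h_bc_pos, other = h_oth)
    ),
    treatments = list(
      chemotherapy = c(anthracycline = 0.80, taxane = 0.70),
      hormone = 0.71,
      trastuzumab = 0.69
    )
  )
}

#' The synthetic model upgraded with progesterone-receptor status
#'
#' Convenience wrapper: [synthetic_model_v22()] with the PR terms of
#' [pr_biomarker_terms()] incorporated per ER stratum and the version label
#' bumped to `"2.3"`.
#'
#' @param terms Per-stratum PR terms; defaults to [pr_biomarker_terms()].
#' @return A [pb_model()] labelled `"2.3"`.
#' @export
synthetic_model_v23 <- function(terms = pr_biomarker_terms()) {
  incorporate_biomarker(synthetic_model_v22(), terms, version = "2.3")
}
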