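---
title: "An ER-stratified absolute-risk engine and the mean-unity biomarker incorporation procedure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ER-stratified absolute-risk engine and the mean-unity biomarker incorporation procedure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prbreast)
```

## The model

`prbreast` implements the kind of absolute-risk prognostic engine used for
early invasive breast cancer: separate cause-specific proportional-hazards
models for breast-cancer mortality and other-cause mortality, stratified by
oestrogen-receptor (ER) status.  A patient's prognostic index (PI) is a log
relative hazard,

$$\mathrm{PI} = \sum_k \beta_k\, g_k(x_k) \;+\; \sum_b \log \mathrm{HR}_b(\text{status}_b),$$

where the first sum runs over clinico-pathological covariates (age, tumour
size, grade, positive nodes, mode of detection) with per-covariate
transformations $g_k$, and the second over attached biomarker terms (HER2,
KI67 and — after incorporation — PR).  Cumulative cause-specific mortality
is obtained by applying $e^{\mathrm{PI}}$ (times treatment relative hazards,
for the breast cause) to a baseline cumulative hazard $H_0(t)$ tabulated on
a yearly grid over 0–15 years.

### Competing-risk partition

The engine discretises time into years.  Within year $j$ the adjusted
increments are $dH_{bc,j}$ and $dH_{oth,j}$; the probability of dying in the
year is $S_{j-1}\,(1 - e^{-(dH_{bc,j}+dH_{oth,j})})$ and is attributed to
each cause in proportion to its increment.  This yearly convention matches
how such tools report 5-, 10- and 15-year risks.  For *constant* hazards the
partition is exact: the engine reproduces the closed form
$F_{bc}(t) = \frac{\lambda_1}{\lambda_1+\lambda_2}(1-e^{-(\lambda_1+\lambda_2)t})$
to numerical precision, which the test suite verifies against a 10,000-step
numerical integration.  All-cause mortality is the exact sum of the two
cause components.  Treatment relative hazards multiply the breast-cause
hazard *before* the partition; the alternative (partitioning first) is not
used because treatment acts on the hazard scale in the underlying Cox
formulation.

### Incorporating a biomarker without refitting

The baseline hazards were (notionally) estimated in a population with
unknown biomarker status, i.e. they describe a patient with *average*
status.  An externally estimated hazard ratio $\mathrm{HR}$ (positive versus
negative) with positivity prevalence $p$ is therefore centred so that the
prevalence-weighted **arithmetic** mean of the per-level hazard ratios is
exactly one:

$$\mathrm{HR}_{neg} = \frac{1}{p\,\mathrm{HR} + (1-p)},\qquad
  \mathrm{HR}_{pos} = \frac{\mathrm{HR}}{p\,\mathrm{HR} + (1-p)}.$$

Missing status keeps the population average (multiplier 1).  The arithmetic
convention — rather than centring on the log scale — is deliberate: it is
the convention under which a cohort with the stated prevalence has an
average hazard multiplier of one, so the baseline hazard needs no change,
and it is the convention that reproduces the published per-level values for
the PR terms (1.03/0.80 in ER-negative disease from HR 0.77 at 14%
positivity; 1.30/0.94 in ER-positive disease from HR 0.72 at 83%).  A
log-scale mean would give 1.31/0.95 for the ER-positive pair.
`incorporate_biomarker()` attaches the rescaled term and touches nothing
else — the version label aside, every other coefficient and both baseline
hazards are carried over bit for bit.

```{r rescale}
pr_biomarker_terms()
```

### Estimating the biomarker effect

`fit_pr_offset_cox()` estimates the conditional effect of PR positivity by
maximising the study-stratified Cox partial likelihood in a single free
parameter, with the existing model's PI entering as an offset — its
coefficient constrained to one.  Risk sets honour delayed entry (left
truncation) for prevalent cases and censoring at 15 years.  Conventions the
literature leaves open and our choices:

* **Ties** — Efron's approximation by default (ties are plausible when
  follow-up is recorded coarsely); Breslow available by flag, and the two
  are oracle-tested to agree on tie-free data.
* **Tests and intervals** — Wald throughout (the interval and p reported
  with a hazard ratio are typically Wald); a likelihood-ratio flavour of
  the interaction test is available by flag and agrees with Wald to within
  simulation error in the tests.
* **Age in interactions** — per 5 years, matching the usual reporting of
  the age effect.

Between-study heterogeneity uses Cochran's Q with inverse-variance weights
over per-study log hazard ratios; proportional-hazards diagnostics are
scaled Schoenfeld residuals with the correlation-with-time test.

## The synthetic cohorts

No patient-level data from the source consortium or registry are
distributable, so the package ships seeded generators whose **defaults are
the study conditions** rather than tuning knobs:

* `bcac_config()` emulates a 49-study estimation consortium: age 57.1
  (sd 11.9) truncated to 25–85; tumour size mean 2.1 cm (sd 1.5, log-normal,
  capped at 20 cm); grade mix 19.5/48.7/31.8%; nodes with mean 1.2 and
  sd 2.7 (negative binomial, capped at 20); joint ER/PR cells 16.6/2.6/13.8/
  67.0% (equivalently 14% PR positivity within ER-negative and 83% within
  ER-positive disease); HER2 positive 16.1% with 28.3% missing; detection
  mode missing for 46.6% with ~10% screen-detected among observed;
  diagnoses 1990–2017 with administrative end of study 2018; 30% prevalent
  cases with exponential entry delay (mean 1.5 y, a value chosen as
  realistic for consortium enrolment since no delay distribution is
  published); true conditional PR log hazard ratios log(0.77)/log(0.72) per
  ER stratum.
* `nz_config()` emulates a population registry: diagnoses 2000–2014,
  administrative censoring at 2014-12-31, ethnicity strata (9.3% Māori,
  5.9% Pacific, 72.3% European, 11.0% other, 1.5% missing), 42.7%
  screen-detected with no missingness, 35% chemotherapy recorded only as a
  yes/no flag, and no trastuzumab record — forcing the treatment-assumption
  rules through `assign_nz_treatments()` exactly as a validation pipeline
  must.

Survival times are drawn by exact inversion of the yearly
piecewise-constant cause-specific hazards implied by the model, so the
generator itself carries no discretisation bias, and prevalent cases are
redrawn conditional on being alive at entry, making left-truncated risk
sets the correct likelihood.  One top-level seed fans out to named
sub-streams per component, so adding a component leaves unrelated draws
untouched.  The breast-cause baseline of the synthetic fixture model was
calibrated once so that the default estimation cohort experiences about 11
breast-cancer deaths per 1000 person-years, and then frozen.

What the generators do *not* emulate: assay-level measurement error and
between-study differences in positivity definitions, non-European ancestry
effects, non-administrative loss to follow-up, and any correlation between
treatment assignment and unmeasured prognosis.  Tests passing on these
cohorts therefore demonstrate internal consistency of the machinery — not
that the synthetic fixture model is a good model of any real population.

## The fixture model

The published tool's coefficient values and baseline-hazard parameters are
configuration, not code: they live in a YAML tree
(`read_model_config()` / `write_model_config()`) with the version label,
per-stratum terms, biomarkers stored as raw hazard ratio plus prevalence,
and yearly baseline cumulative hazards.  The repository ships a clearly
labelled **synthetic** fixture (`synthetic_model_v22()`,
`inst/extdata/model_synthetic_v22.yaml`) with plausible effect directions
and magnitudes so every stage is exercisable end to end; it is not the
published value set.

## Validation conventions

* **Expected deaths** sum each patient's predicted cumulative mortality at
  their own horizon: observed follow-up for survivors, *potential*
  follow-up (diagnosis to the administrative censor date, as if the patient
  had survived) for deaths, capped at 15 years.  Under purely
  administrative censoring this makes the expected count an unbiased
  predictor of the observed count, which is what the self-calibration
  property tests exploit.
* **Goodness of fit** is $\chi^2 = (O-P)^2/P$ on 1 degree of freedom — the
  predicted count in the denominator.  This convention is pinned by the
  worked examples in the test suite; the observed-denominator variant fails
  them.
* **Discrimination** treats death from breast cancer within the 15-year
  window as the binary case label (other-cause deaths and survivors are
  non-cases) and uses the Mann–Whitney AUC with tied scores counted half;
  a censoring-aware time-dependent AUC is out of scope.  Risk can be scored
  either at a fixed 15-year horizon (default, and what an AUC over a fixed
  window implies) or at each patient's own horizon; both are exposed since
  published analyses rarely say which was used.
* **DeLong comparison** of the two model versions uses placement values;
  identical rankings yield a difference of 0 with p = 1 and a warning
  rather than a division by zero.
* **Quintile calibration** bins by quantile of predicted risk and shows
  the simple observed proportion with a Wilson 95% CI per bin (a
  Kaplan–Meier variant is available by flag); degenerate constant
  predictions collapse to fewer bins rather than failing.  The simple
  proportion is only an estimate of the predicted quantity when follow-up
  is complete, which is how the calibration property test constructs its
  cohort.
* **Reclassification** uses half-open categories $[0,0.15)$, $[0.15,0.20)$,
  $[0.20,1]$ of predicted 10-year breast-cancer mortality, with the top
  category closed.
* Reported hazard ratios round half-even to 2 decimals and report
  percentages to 1 decimal; internal arithmetic is unrounded.

## Eligibility, imputation and treatment rules

Eligibility rules run sequentially in a fixed order (age 25–85, size ≤ 20
cm, ≤ 20 nodes, then cohort-flavour-specific rules), so a record failing
several rules is tallied once at the first — making exclusion tallies
reproducible.  "Inconsistent follow-up" flags both negative times and
follow-up before entry, since either makes a record unusable.  Missing
detection mode is imputed by the age rule (under 50 or over 70 → clinically
detected) with mean imputation of the screen indicator for the remaining
50–70 age band; the imputation preserves the mean of the indicator in that
band by construction.  Registry treatment resolution uses a calendar cut at
2010: chemotherapy before 2010 is assumed anthracycline-based, from 2010
onward taxane-based, and trastuzumab is assumed for HER2-positive patients
diagnosed after 2010; two sensitivity policies (all-anthracycline;
all-HER2-positive-treated) mirror the usual sensitivity analyses.  Hormone
therapy multiplies the breast-cause hazard only in ER-positive disease.

## Numerical choices and problem sizes

Baseline cumulative hazards are linearly interpolated within years
(piecewise-constant hazard), horizons are validated to $[0,15]$, and the
partial-likelihood fits delegate to `survival::coxph` (Efron ties), which
the tests pin against a hand-coded brute-force maximisation on all
instances with ≤ 10 subjects.  The property-style tests use cohorts of
2,000–30,000 synthetic patients and 20–100 seeds per property — sizes at
which the Monte-Carlo error of each property is comfortably below its
asserted bound while the whole suite stays desk-scale.

## Known limitations

The engine's other-cause model depends on age only; the fixture's
treatment effects are synthetic constants without regimen-era refinement;
bisphosphonate and extended-endocrine benefits are out of scope; and
calibration of any such model against a real registry depends on the
baseline hazard matching that population and period — the machinery here
measures such miscalibration but cannot remove it.
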