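#' Default chronic condition groups
#'
#' The twelve ICD-10 chronic-condition groups used when none are supplied:
#' cancer, cardiovascular, dermatological, digestive, endocrine,
#' musculoskeletal, neurological, psychiatric, respiratory, sensorial,
#' sequelae of injury and urological.
#'
#' @return Character vector of twelve group identifiers.
#' @export
default_conditions <- function() {
  c("cancer", "cardiovascular", "dermatological", "digestive", "endocrine",
    "musculoskeletal", "neurological", "psychiatric", "respiratory",
    "sensorial", "sequelae_of_injury", "urological")
}

# Adult household prevalence of each group (proportion of the overall adult
# population reporting the group), used as generator defaults.
default_condition_prevalence <- function() {
  c(cancer = 0.019, cardiovascular = 0.212, dermatological = 0.062,
    digestive = 0.046, endocrine = 0.188, musculoskeletal = 0.287,
    neurological = 0.101, psychiatric = 0.063, respiratory = 0.115,
    sensorial = 0.654, sequelae_of_injury = 0.035, urological = 0.048)
}

covariate_columns <- function() {
  c("age_dec", "male", "married", "living_alone",
    "educ_secondary", "educ_tertiary", "urban_small", "urban_large")
}

default_covariate_spec <- function() {
  list(
    age_class_probs = c(`18-40` = 0.377, `40-65` = 0.428, `>65` = 0.195),
    age_max = 95,
    p_male = 0.48,
    p_married = 0.55,
    p_living_alone = 0.15,
    education_probs = c(primary = 0.30, secondary = 0.45, tertiary = 0.25),
    residence_probs = c(rural = 0.23, urban_small = 0.46, urban_large = 0.31)
  )
}

#' Specify one logistic outcome-generating model
#'
#' Building block for the `disability_models` field of a
#' [population_spec()]: the logistic model generating one disability
#' outcome, with per-condition and per-covariate log odds ratios. An `NA`
#' intercept is calibrated at generation time so the population mean
#' outcome probability equals `target_rate`.
#'
#' @param condition_log_or Named log odds ratios, one per condition.
#' @param covariate_log_or Named log odds ratios over the covariate design
#'   columns (age in decades centred at 50, male, married, living alone,
#'   secondary/tertiary education, small/large urban residence).
#' @param intercept Fixed intercept, or `NA` to calibrate.
#' @param target_rate Marginal outcome probability used when calibrating.
#' @return List describing the model.
#' @export
outcome_model <- function(condition_log_or, covariate_log_or,
                          intercept = NA_real_, target_rate = NULL) {
  list(intercept = intercept, target_rate = target_rate,
       condition_log_or = condition_log_or,
       covariate_log_or = covariate_log_or)
}

default_disability_models <- function(condition_names) {
  cov_dis <- c(age_dec = 0.55, male = -0.10, married = -0.20,
               living_alone = 0.25, educ_secondary = -0.15,
               educ_tertiary = -0.35, urban_small = 0.05, urban_large = -0.05)
  cov_sev <- c(age_dec = 0.70, male = -0.05, married = -0.25,
               living_alone = 0.30, educ_secondary = -0.10,
               educ_tertiary = -0.30, urban_small = 0.05, urban_large = -0.05)
  cov_self <- c(age_dec = 0.25, male = 0.00, married = -0.15,
                living_alone = 0.20, educ_secondary = -0.20,
                educ_tertiary = -0.40, urban_small = 0.05, urban_large = 0.00)
  b_dis <- c(cancer = 0.50, cardiovascular = 0.90, dermatological = 0.20,
             digestive = 0.35, endocrine = 0.60, musculoskeletal = 1.10,
             neurological = 1.70, psychiatric = 1.30, respiratory = 0.30,
             sensorial = 0.15, sequelae_of_injury = 0.80, urological = 1.20)
  b_sev <- c(cancer = 0.50, cardiovascular = 1.00, dermatological = 0.10,
             digestive = 0.30, endocrine = 0.50, musculoskeletal = 0.10,
             neurological = 2.20, psychiatric = 1.20, respiratory = 0.25,
             sensorial = 0.05, sequelae_of_injury = 0.80, urological = 1.60)
  b_self <- c(cancer = 0.60, cardiovascular = 0.80, dermatological = 0.25,
              digestive = 0.40, endocrine = 0.70, musculoskeletal = 1.30,
              neurological = 1.00, psychiatric = 1.40, respiratory = 0.45,
              sensorial = 0.90, sequelae_of_injury = 0.90, urological = 0.50)
  trim <- function(b) b[condition_names]
  list(
    disabled = outcome_model(trim(b_dis), cov_dis, target_rate = 0.039),
    severely_disabled = outcome_model(trim(b_sev), cov_sev, target_rate = 0.014),
    self_reported = outcome_model(trim(b_self), cov_self, target_rate = 0.120)
  )
}

default_design_spec <- function(n_areas = 11) {
  list(n_areas = n_areas,
       severity_fraction = c(0.10, 0.20, 0.50, 0.90),
       area_multiplier = rep(1, n_areas),
       mode = "bernoulli")
}

default_nonresponse_spec <- function() {
  list(intercept = NA_real_, target_rate = 0.766,
       coef = c(severity = -0.15, age_dec = -0.05, living_alone = -0.30))
}

#' Specify a synthetic survey population
#'
#' Collects every generative parameter of the synthetic population and its
#' two-stage stratified survey design: condition prevalences and their
#' co-morbidity structure (a shared Gaussian latent frailty with
#' per-condition loadings), socio-demographic covariates, the logistic
#' disability-generating models for the three outcomes, the ADL item rule,
#' the stratified design (4 presumed-severity levels crossed with geographic
#' areas, unequal sampling fractions) and the covariate-dependent
#' non-response model.
#'
#' Defaults emulate a national disability survey of the adult household
#' population: twelve ICD-10 condition groups at their published adult
#' prevalences, marginal outcome rates calibrated to 3.9% (ADL disability),
#' 1.4% (severe disability) and 12.0% (self-reported disability), and a
#' 76.6% marginal response rate.
#'
#' @param population_size Number of persons in the full population.
#' @param condition_names Unique identifiers of the chronic-condition groups.
#' @param marginal_prevalence Named per-condition marginal probability in (0,1).
#' @param comorbidity_loading Per-condition loading in `[0,1)` on the shared
#'   latent frailty; pairwise condition correlation increases with the
#'   product of loadings. Recycled if scalar.
#' @param covariates List of covariate distributions (see
#'   `default_covariate_spec()` for the shape).
#' @param disability_models Named list with elements `disabled`,
#'   `severely_disabled`, `self_reported`, each an `outcome_model()`-shaped
#'   list (intercept, `target_rate`, `condition_log_or`, `covariate_log_or`).
#'   An `NA` intercept is calibrated so the population mean outcome
#'   probability equals `target_rate`.
#' @param adl_model List with `p_extra_item`: probability that each further
#'   ADL item of a disabled person is also restricted.
#' @param design List with `n_areas`, per-severity `severity_fraction` in
#'   (0,1], per-area `area_multiplier`, and sampling `mode`
#'   (`"bernoulli"` or `"fixed"`).
#' @param nonresponse List with logistic response-model coefficients
#'   (`severity`, `age_dec`, `living_alone`), plus `intercept` (`NA` =
#'   calibrate) and `target_rate` for the marginal response rate.
#' @param inclusive_forty Age-class boundary convention; see
#'   [assign_age_class()].
#' @param seed Master integer seed; per-stage child seeds are derived
#'   deterministically from it.
#' @return A validated list of class `population_spec`.
#' @export
population_spec <- function(population_size = 50000,
                            condition_names = default_conditions(),
                            marginal_prevalence = NULL,
                            comorbidity_loading = 0.5,
                            covariates = default_covariate_spec(),
                            disability_models = NULL,
                            adl_model = list(p_extra_item = 0.3),
                            design = default_design_spec(),
                            nonresponse = default_nonresponse_spec(),
                            inclusive_forty = FALSE,
                            seed = 1L) {
  if (is.null(marginal_prevalence)) {
    marginal_prevalence <- default_condition_prevalence()[condition_names]
    if (anyNA(marginal_prevalence)) {
      stop("`marginal_prevalence` must be supplied for non-default ",
           "`condition_names`", call. = FALSE)
    }
  }
  if (is.null(names(marginal_prevalence))) {
    names(marginal_prevalence) <- condition_names
  }
  if (length(comorbidity_loading) == 1) {
    comorbidity_loading <- rep(comorbidity_loading, length(condition_names))
  }
  names(comorbidity_loading) <- condition_names
  if (is.null(disability_models)) {
    disability_models <- default_disability_models(condition_names)
  }
  spec <- structure(
    list(population_size = population_size,
         condition_names = condition_names,
         marginal_prevalence = marginal_prevalence,
         comorbidity_loading = comorbidity_loading,
         covariates = covariates,
         disability_models = disability_models,
         adl_model = adl_model,
         design = design,
         nonresponse = nonresponse,
         inclusive_forty = isTRUE(inclusive_forty),
         seed = as.integer(seed)),
    class = "population_spec")
  validate_population_spec(spec)
  spec
}

validate_population_spec <- function(spec) {
  with(spec, {
    if (!is.numeric(population_size) || length(population_size) != 1 ||
        population_size < 1) {
      stop("invalid `population_size`", call. = FALSE)
    }
    if (anyDuplicated(condition_names)) {
      stop("`condition_names` must be unique", call. = FALSE)
    }
    assert_probability(marginal_prevalence, "marginal_prevalence",
                       open_low = FALSE, open_high = FALSE)
    if (any(comorbidity_loading < 0 | comorbidity_loading >= 1)) {
      stop("`comorbidity_loading` must lie in [0,1)", call. = FALSE)
    }
    frac <- design$severity_fraction
    if (length(frac) != 4 || any(frac <= 0 | frac > 1)) {
      stop("`design$severity_fraction` must be 4 values in (0,1]",
           call. = FALSE)
    }
    if (length(design$area_multiplier) != design$n_areas) {
      stop("`design$area_multiplier` must have length `design$n_areas`",
           call. = FALSE)
    }
    for (nm in c("disabled", "severely_disabled", "self_reported")) {
      m <- disability_models[[nm]]
      if (is.null(m)) {
        stop(sprintf("`disability_models` is missing outcome `%s`", nm),
             call. = FALSE)
      }
      if (!all(condition_names %in% names(m$condition_log_or))) {
        stop(sprintf(
          "`disability_models$%s$condition_log_or` must cover every condition",
          nm), call. = FALSE)
      }
      if (!all(covariate_columns() %in% names(m$covariate_log_or))) {
        stop(sprintf(
          "`disability_models$%s$covariate_log_or` must cover every covariate",
          nm), call. = FALSE)
      }
    }
  })
  invisible(spec)
}
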