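# Shared builders for small synthetic-survey specifications and toy
# subset-AF evaluators.

cov_cols <- c("age_dec", "male", "married", "living_alone",
              "educ_secondary", "educ_tertiary", "urban_small", "urban_large")

cov_zero <- function() setNames(rep(0, length(cov_cols)), cov_cols)

make_models <- function(beta, cov_eff = cov_zero(),
                        targets = c(disabled = 0.10,
                                    severely_disabled = 0.04,
                                    self_reported = 0.12),
                        intercepts = NULL) {
  mk <- function(nm, scale) {
    aafsurvey::outcome_model(
      beta * scale, cov_eff,
      intercept = if (is.null(intercepts)) NA_real_ else intercepts[[nm]],
      target_rate = if (is.null(intercepts)) targets[[nm]] else NULL)
  }
  list(disabled = mk("disabled", 1),
       severely_disabled = mk("severely_disabled", 0.8),
       self_reported = mk("self_reported", 0.9))
}

make_test_spec <- function(n = 5000, k = 2,
                           prevalence = rep(0.3, k),
                           loading = rep(0, k),
                           beta = rep(1, k),
                           cov_eff = cov_zero(),
                           targets = c(disabled = 0.10,
                                       severely_disabled = 0.04,
                                       self_reported = 0.12),
                           intercepts = NULL,
                           severity_fraction = c(0.3, 0.5, 0.8, 1.0),
                           n_areas = 2,
                           response_target = 0.8,
                           seed = 42) {
  conds <- paste0("c", seq_len(k))
  population_spec(
    population_size = n,
    condition_names = conds,
    marginal_prevalence = setNames(prevalence, conds),
    comorbidity_loading = setNames(loading, conds),
    disability_models = make_models(setNames(beta, conds), cov_eff,
                                    targets, intercepts),
    design = list(n_areas = n_areas, severity_fraction = severity_fraction,
                  area_multiplier = rep(1, n_areas), mode = "bernoulli"),
    nonresponse = list(intercept = NA_real_, target_rate = response_target,
                       coef = c(severity = -0.15, age_dec = -0.05,
                                living_alone = -0.30)),
    seed = seed)
}

# Evaluator backed by a random table over all 2^k subsets, AF(empty) = 0.
random_af_evaluator <- function(k) {
  af <- c(0, runif(2^k - 1, -0.2, 0.9))
  function(subset) {
    mask <- if (length(subset)) sum(2^(subset - 1)) else 0
    af[mask + 1]
  }
}

quiet_survey <- function(spec) suppressMessages(simulate_survey(spec))
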