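# Model-matrix columns for the generating models, from a covariate table.
covariate_design <- function(df) {
  cbind(
    age_dec = (df$age - 50) / 10,
    male = as.numeric(df$sex == "male"),
    married = as.numeric(df$marital_status == "married"),
    living_alone = as.numeric(df$living_alone),
    educ_secondary = as.numeric(df$education == "secondary"),
    educ_tertiary = as.numeric(df$education == "tertiary"),
    urban_small = as.numeric(df$residence == "urban_small"),
    urban_large = as.numeric(df$residence == "urban_large")
  )
}

# Solve the intercept so that mean(plogis(b0 + eta)) == target.
calibrate_intercept <- function(eta, target) {
  uniroot(function(b0) mean(plogis(b0 + eta)) - target,
          interval = c(-40, 40), tol = 1e-12)$root
}

# Linear predictor (no intercept) of one outcome model.
outcome_eta <- function(model, cond_mat, cov_mat) {
  beta <- model$condition_log_or[colnames(cond_mat)]
  gamma <- model$covariate_log_or[colnames(cov_mat)]
  drop(cond_mat %*% beta + cov_mat %*% gamma)
}

#' Generate a synthetic population
#'
#' Draws the full household population described by a [population_spec()]:
#' socio-demographic covariates, correlated chronic-condition indicators via
#' a shared Gaussian latent frailty (Gaussian copula, exact marginal
#' prevalences), the three disability outcomes from their logistic models,
#' the six ADL item scores consistent with outcome status, and the presumed
#' disability severity level (1-4) that drives the stratified design.
#'
#' The two ADL-based outcomes are coupled comonotonically (one shared
#' uniform), with the severe-outcome probability truncated at the
#' disability probability, so that severe disability always implies
#' disability.
#'
#' @param spec A [population_spec()].
#' @return Tibble with one row per person: identifiers, design fields
#'   (`area_id`, `presumed_severity`, `stratum_id`), covariates,
#'   `cond_<name>` indicators, `adl_1`..`adl_6`, `self_report` answer and
#'   the three generated outcome flags. The realized generating model
#'   (calibrated intercepts) is attached as attribute `"truth"`.
#' @export
generate_population <- function(spec) {
  validate_population_spec(spec)
  set.seed(spec$seed)
  n <- spec$population_size
  k <- length(spec$condition_names)
  cv <- spec$covariates

  age_class <- sample(names(cv$age_class_probs), n, replace = TRUE,
                      prob = cv$age_class_probs)
  age <- numeric(n)
  age[age_class == "18-40"] <- runif(sum(age_class == "18-40"), 18, 40)
  age[age_class == "40-65"] <- runif(sum(age_class == "40-65"), 40, 65)
  age[age_class == ">65"] <- runif(sum(age_class == ">65"), 65, cv$age_max)

  pop <- tibble::tibble(
    person_id = seq_len(n),
    area_id = sample.int(spec$design$n_areas, n, replace = TRUE),
    age = age,
    sex = ifelse(runif(n) < cv$p_male, "male", "female"),
    marital_status = ifelse(runif(n) < cv$p_married, "married", "unmarried"),
    living_alone = runif(n) < cv$p_living_alone,
    education = sample(names(cv$education_probs), n, replace = TRUE,
                       prob = cv$education_probs),
    residence = sample(names(cv$residence_probs), n, replace = TRUE,
                       prob = cv$residence_probs)
  )
  pop$age_class <- assign_age_class(pop$age, spec$inclusive_forty)

  # Correlated condition indicators: X_j = 1{lam_j U + sqrt(1-lam_j^2) Z_j
  # <= qnorm(p_j)} keeps marginals exact for any loading.
  frailty <- rnorm(n)
  cond <- matrix(FALSE, n, k, dimnames = list(NULL, spec$condition_names))
  for (j in seq_len(k)) {
    lam <- spec$comorbidity_loading[j]
    latent <- lam * frailty + sqrt(1 - lam^2) * rnorm(n)
    cond[, j] <- latent <= qnorm(spec$marginal_prevalence[j])
  }

  cov_mat <- covariate_design(pop)
  cond_num <- cond * 1
  models <- spec$disability_models
  etas <- lapply(models, outcome_eta, cond_mat = cond_num, cov_mat = cov_mat)
  intercepts <- vapply(names(models), function(nm) {
    m <- models[[nm]]
    if (is.na(m$intercept)) calibrate_intercept(etas[[nm]], m$target_rate)
    else m$intercept
  }, numeric(1))

  p_dis <- plogis(intercepts[["disabled"]] + etas[["disabled"]])
  p_sev <- pmin(plogis(intercepts[["severely_disabled"]] +
                         etas[["severely_disabled"]]), p_dis)
  p_self <- plogis(intercepts[["self_reported"]] + etas[["self_reported"]])

  u_adl <- runif(n)
  disabled <- u_adl < p_dis
  severe <- u_adl < p_sev
  self_rep <- runif(n) < p_self

  adl <- draw_adl_items(disabled, severe, spec$adl_model$p_extra_item)
  colnames(adl) <- paste0("adl_", 1:6)

  pop <- dplyr::bind_cols(
    pop,
    tibble::as_tibble(cond_num * 1L) |>
      rlang::set_names(paste0("cond_", spec$condition_names)),
    tibble::as_tibble(adl)
  )
  pop$self_report <- self_rep
  pop$disabled <- disabled
  pop$severely_disabled <- severe
  pop$self_reported <- self_rep
  pop$presumed_severity <- ifelse(severe, 4L,
                           ifelse(disabled, 3L,
                           ifelse(self_rep, 2L, 1L)))
  pop$stratum_id <- paste0("s", pop$presumed_severity, "_a", pop$area_id)
  attr(pop, "truth") <- list(intercepts = intercepts, spec = spec)
  pop
}

# ADL item scores consistent with the generated flags: non-disabled persons
# score 0 everywhere; disabled persons have one primary restricted item
# (score 4 if severe, else 1-3) and each further item restricted with
# probability p_extra at score 1-3.
draw_adl_items <- function(disabled, severe, p_extra) {
  n <- length(disabled)
  adl <- matrix(0L, n, 6)
  idx <- which(disabled)
  if (length(idx)) {
    primary <- sample.int(6, length(idx), replace = TRUE)
    extra <- matrix(runif(length(idx) * 6) < p_extra, ncol = 6)
    scores <- matrix(sample.int(3, length(idx) * 6, replace = TRUE), ncol = 6)
    block <- ifelse(extra, scores, 0L)
    block[cbind(seq_along(idx), primary)] <-
      ifelse(severe[idx], 4L, sample.int(3, length(idx), replace = TRUE))
    adl[idx, ] <- block
  }
  storage.mode(adl) <- "integer"
  adl
}

#' Draw a stratified survey sample
#'
#' Samples the population within strata defined by presumed severity level
#' crossed with geographic area. The per-stratum sampling fraction is the
#' severity-level fraction times the area multiplier (capped at 1),
#' emulating oversampling of the most severely disabled and of intensively
#' sampled areas. Design weights are the inverse of the sampling fraction.
#'
#' @param population Output of [generate_population()].
#' @param spec The same [population_spec()].
#' @param seed Stage seed; defaults to a child of `spec$seed`.
#' @return Tibble of sampled records with `sampling_fraction` and
#'   `design_weight` set.
#' @export
draw_sample <- function(population, spec, seed = NULL) {
  set.seed(seed %||% child_seed(spec$seed, 1))
  frac_sev <- spec$design$severity_fraction
  mult <- spec$design$area_multiplier
  f <- pmin(frac_sev[population$presumed_severity] *
              mult[population$area_id], 1)
  if (any(f <= 0)) {
    stop("sampling fraction 0 for a stratum with members", call. = FALSE)
  }
  if (identical(spec$design$mode, "fixed")) {
    keep <- logical(nrow(population))
    for (st in unique(population$stratum_id)) {
      rows <- which(population$stratum_id == st)
      n_take <- round(f[rows[1]] * length(rows))
      keep[sample(rows, n_take)] <- TRUE
    }
  } else {
    keep <- runif(nrow(population)) < f
  }
  out <- population[keep, , drop = FALSE]
  out$sampling_fraction <- f[keep]
  out$design_weight <- 1 / out$sampling_fraction
  out
}

#' Apply covariate-dependent non-response
#'
#' Draws a `responded` flag per sampled record from the logistic response
#' model of the spec (coefficients on presumed severity, age and living
#' alone). An `NA` intercept is calibrated on the sample's linear
#' predictors so that the expected marginal response rate equals
#' `nonresponse$target_rate`. The realized response rate is reported via
#' `message()`.
#'
#' @param sample Output of [draw_sample()].
#' @param spec The same [population_spec()].
#' @param seed Stage seed; defaults to a child of `spec$seed`.
#' @return `sample` with logical `responded` added.
#' @export
apply_nonresponse <- function(sample, spec, seed = NULL) {
  set.seed(seed %||% child_seed(spec$seed, 2))
  nr <- spec$nonresponse
  eta <- nr$coef[["severity"]] * (sample$presumed_severity - 1) +
    nr$coef[["age_dec"]] * (sample$age - 50) / 10 +
    nr$coef[["living_alone"]] * as.numeric(sample$living_alone)
  b0 <- if (is.na(nr$intercept)) calibrate_intercept(eta, nr$target_rate)
        else nr$intercept
  p <- plogis(b0 + eta)
  sample$responded <- runif(nrow(sample)) < p
  message(sprintf("response rate: %.3f (%d of %d)",
                  mean(sample$responded), sum(sample$responded),
                  nrow(sample)))
  sample
}

#' Simulate a complete survey
#'
#' Convenience wrapper: population, stratified sample and non-response in
#' one call, plus calibration margins (area x age class x sex marginal
#' population totals) taken from the generated population.
#'
#' @param spec A [population_spec()].
#' @return List with `population`, `sample` (with `responded`), `margins`
#'   (tibble `variable`, `category`, `target_total`) and `truth`.
#' @export
simulate_survey <- function(spec) {
  population <- generate_population(spec)
  sample <- draw_sample(population, spec)
  sample <- apply_nonresponse(sample, spec)
  margins <- population_margins(population)
  list(population = population, sample = sample, margins = margins,
       truth = attr(population, "truth"))
}

#' Marginal population totals for calibration
#'
#' @param population A population table.
#' @param variables Margin variables (default area, age class, sex).
#' @return Tibble with columns `variable`, `category`, `target_total`.
#' @export
population_margins <- function(population,
                               variables = c("area_id", "age_class", "sex")) {
  purrr::map_dfr(variables, function(v) {
    tab <- table(population[[v]])
    tibble::tibble(variable = v, category = names(tab),
                   target_total = as.numeric(tab))
  })
}

#' Ground-truth average attributable fractions
#'
#' Computes the true AAF of each condition under the known generating model
#' by large-sample g-computation on the generated population: for every
#' subset S of conditions, outcome probabilities are recomputed with the
#' conditions in S set to absent, `AF(S) = 1 - E[p(S -> 0)] / E[p]`, and
#' the per-condition AAFs are the Shapley combination of the subset AFs
#' (see [aaf_exact()]).
#'
#' @param spec A [population_spec()].
#' @param definition One of `"disabled"`, `"severely_disabled"`,
#'   `"self_reported"`.
#' @param age_class Optional single age class to restrict to.
#' @param population Optional pre-generated population (must carry the
#'   `"truth"` attribute); generated from `spec` if omitted.
#' @param conditions Conditions forming the factor set; defaults to all.
#' @return Named numeric vector of true AAFs with attribute `"af_all"`,
#'   the joint AF of eliminating every condition in the set.
#' @export
true_aaf_oracle <- function(spec,
                            definition = c("disabled", "severely_disabled",
                                           "self_reported"),
                            age_class = NULL, population = NULL,
                            conditions = NULL) {
  definition <- match.arg(definition)
  conditions <- conditions %||% spec$condition_names
  k <- length(conditions)
  if (k > 12) {
    stop("exact oracle limited to k <= 12 conditions; use the Monte Carlo ",
         "mode of the estimator instead", call. = FALSE)
  }
  if (is.null(population)) population <- generate_population(spec)
  truth <- attr(population, "truth")
  if (is.null(truth)) stop("`population` lacks the generator truth attribute",
                           call. = FALSE)
  rows <- if (is.null(age_class)) seq_len(nrow(population))
          else which(population$age_class == age_class)
  df <- population[rows, , drop = FALSE]
  cond_mat <- as.matrix(df[paste0("cond_", spec$condition_names)])
  colnames(cond_mat) <- spec$condition_names
  cov_mat <- covariate_design(df)
  models <- spec$disability_models
  b0 <- truth$intercepts
  eta <- lapply(names(models), function(nm) {
    b0[[nm]] + outcome_eta(models[[nm]], cond_mat, cov_mat)
  })
  names(eta) <- names(models)

  p_for <- function(drop_sets) {
    # drop_sets: named list outcome -> per-row eta reduction
    p_dis <- plogis(eta$disabled - drop_sets$disabled)
    switch(definition,
      disabled = p_dis,
      self_reported = plogis(eta$self_reported - drop_sets$self_reported),
      severely_disabled = pmin(
        plogis(eta$severely_disabled - drop_sets$severely_disabled), p_dis))
  }
  contrib <- lapply(names(models), function(nm) {
    beta <- models[[nm]]$condition_log_or[conditions]
    sweep(cond_mat[, conditions, drop = FALSE], 2, beta, `*`)
  })
  names(contrib) <- names(models)
  zero <- rep(0, nrow(df))
  p_obs <- p_for(list(disabled = zero, severely_disabled = zero,
                      self_reported = zero))
  denom <- mean(p_obs)
  evaluator <- function(subset) {
    if (!length(subset)) return(0)
    drop_sets <- lapply(contrib, function(cm) {
      rowSums(cm[, subset, drop = FALSE])
    })
    1 - mean(p_for(drop_sets)) / denom
  }
  aaf <- aaf_exact(evaluator, k, factor_names = conditions)
  attr(aaf, "af_all") <- evaluator(seq_len(k))
  aaf
}
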