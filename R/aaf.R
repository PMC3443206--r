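#' Fit the weighted disability model
#'
#' Survey-weighted logistic regression of a binary disability outcome on
#' all factor indicators plus adjustment covariates, fitted by maximum
#' quasi-likelihood (point estimates identical to weighted binomial ML).
#'
#' @param data Respondent table.
#' @param outcome Name of the logical/0-1 outcome column.
#' @param factors Factor identifiers; indicator columns `cond_<name>` (or
#'   bare names if present) must be binary.
#' @param covariates Character vector of adjustment covariate columns
#'   (may be empty).
#' @param weights Name of the weight column; `NULL` for unit weights.
#' @return Object of class `disability_model`: the `glm` fit plus the
#'   factor/covariate bookkeeping needed by the subset evaluator.
#' @export
fit_disability_model <- function(data, outcome, factors,
                                 covariates = character(),
                                 weights = "calibrated_weight") {
  factor_cols <- vapply(factors, function(f) {
    if (f %in% names(data)) f else paste0("cond_", f)
  }, character(1))
  missing_cols <- setdiff(c(factor_cols, covariates, outcome), names(data))
  if (length(missing_cols)) {
    stop("column(s) not in `data`: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (fc in factor_cols) {
    vals <- unique(as.numeric(data[[fc]]))
    if (!all(vals %in% c(0, 1))) {
      stop(sprintf("factor column `%s` is not binary", fc), call. = FALSE)
    }
    if (length(vals) < 2) {
      stop(sprintf("factor `%s` is constant in the data (separation)",
                   names(factor_cols)[factor_cols == fc]), call. = FALSE)
    }
  }
  df <- data
  df$.outcome <- as.numeric(as.logical(df[[outcome]]))
  df$.w <- if (is.null(weights)) rep(1, nrow(df)) else df[[weights]]
  if (any(df$.w < 0)) stop("weights must be nonnegative", call. = FALSE)
  rhs <- paste(c(factor_cols, covariates), collapse = " + ")
  fit <- suppressWarnings(
    glm(as.formula(paste(".outcome ~", rhs)), family = quasibinomial(),
        data = df, weights = df$.w))
  if (!fit$converged) {
    stop("disability model did not converge", call. = FALSE)
  }
  cf <- coef(fit)
  bad <- names(cf)[is.na(cf) | abs(cf) > 15]
  if (length(bad)) {
    stop("separation or aliasing in disability model term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(fit = fit, outcome = outcome, factors = factors,
                 factor_cols = unname(factor_cols), covariates = covariates,
                 weights = weights),
            class = "disability_model")
}

#' @export
print.disability_model <- function(x, ...) {
  cat("Weighted logistic disability model\n")
  cat("  outcome:  ", x$outcome, "\n")
  cat("  factors:  ", paste(x$factors, collapse = ", "), "\n")
  cat("  adjusted: ", if (length(x$covariates))
    paste(x$covariates, collapse = ", ") else "(none)", "\n")
  print(coef(x$fit))
  invisible(x)
}

#' Subset attributable-fraction evaluator by model-based standardization
#'
#' Builds a memoized evaluator of `AF(S)` by g-computation from the fitted
#' disability model: predicted probabilities at the observed data
#' (`p_obs`), and with every factor in `S` set to absent (`p_S`), combined
#' as `AF(S) = 1 - sum(w p_S) / sum(w p_obs)`. The default denominator uses
#' predicted (not observed) weighted cases so `AF(empty) = 0` holds exactly
#' under any model misfit.
#'
#' @param model A [fit_disability_model()] object.
#' @param data Respondent table (defaults to the model's data).
#' @param denominator `"predicted"` (default) or `"observed"` weighted
#'   cases.
#' @return Function mapping an integer subset of `seq_along(factors)` to
#'   `AF(S)`.
#' @export
af_subset_evaluator <- function(model, data = NULL,
                                denominator = c("predicted", "observed")) {
  denominator <- match.arg(denominator)
  fit <- model$fit
  df <- data %||% fit$data
  w <- if (is.null(model$weights)) rep(1, nrow(df)) else df[[model$weights]]
  eta_obs <- predict(fit, newdata = df, type = "link")
  beta <- coef(fit)[model$factor_cols]
  contrib <- sweep(as.matrix(df[model$factor_cols]) * 1, 2, beta, `*`)
  p_obs <- plogis(eta_obs)
  denom <- if (denominator == "predicted") sum(w * p_obs)
           else sum(w * as.numeric(as.logical(df[[model$outcome]])))
  if (denom <= 0) stop("no predicted cases: AF undefined", call. = FALSE)
  k <- length(model$factors)
  memoise_af(function(subset) {
    if (!length(subset) && denominator == "predicted") return(0)
    red <- if (length(subset)) rowSums(contrib[, subset, drop = FALSE])
           else 0
    1 - sum(w * plogis(eta_obs - red)) / denom
  }, k)
}

#' Attributable fraction of eliminating a subset of factors
#'
#' @inheritParams af_subset_evaluator
#' @param subset Factor names or indices to eliminate (may be empty).
#' @return `AF(S)` as a scalar.
#' @export
af_of_subset <- function(model, subset, data = NULL,
                         denominator = "predicted") {
  ev <- af_subset_evaluator(model, data, denominator)
  if (is.character(subset)) subset <- match(subset, model$factors)
  if (anyNA(subset)) stop("unknown factor in `subset`", call. = FALSE)
  ev(as.integer(subset))
}

#' Expected prevented cases
#'
#' Multiplies an average attributable fraction by the weighted number of
#' disabled persons: the expected number of persons whose disability would
#' be prevented by eliminating the condition.
#'
#' @param aaf Average attributable fraction(s).
#' @param n_disabled Weighted total of disabled persons.
#' @param round_to Reporting granularity (default nearest 10,000).
#' @return Tibble with `raw` and `rounded` counts.
#' @export
expected_prevented <- function(aaf, n_disabled, round_to = 10000) {
  raw <- aaf * n_disabled
  tibble::tibble(raw = raw, rounded = round(raw / round_to) * round_to)
}

#' Average attributable fractions for co-morbid factors
#'
#' The central estimator: fits the covariate-adjusted survey-weighted
#' logistic disability model, evaluates subset attributable fractions by
#' model-based standardization, and averages the AF increments over
#' elimination orders — exactly (Shapley-weighted subset enumeration) or by
#' Monte Carlo over sampled permutations.
#'
#' @inheritParams fit_disability_model
#' @param mode `"exact"` (k <= 12) or `"montecarlo"`.
#' @param n_perms Permutations for Monte Carlo mode.
#' @param seed Seed for Monte Carlo mode.
#' @param denominator Passed to [af_subset_evaluator()].
#' @param round_to Reporting granularity of the rounded prevented count.
#' @return Tibble, one row per factor: `factor`, `aaf`, `rank`,
#'   `prevented_raw`, `prevented_rounded` (AAF times the weighted disabled
#'   count). Attributes: `"af_all"` (joint AF of eliminating all factors),
#'   `"sum_aaf"`, `"n_disabled"`, `"mode"`, `"model"`, and for Monte Carlo
#'   `"mc_se"`, `"n_perms"`, `"seed"`.
#' @export
aaf <- function(data, outcome, factors, covariates = character(),
                weights = "calibrated_weight",
                mode = c("exact", "montecarlo"), n_perms = 2000, seed = NULL,
                denominator = "predicted", round_to = 10000) {
  mode <- match.arg(mode)
  k <- length(factors)
  model <- fit_disability_model(data, outcome, factors, covariates, weights)
  ev <- af_subset_evaluator(model, data, denominator)
  if (mode == "exact") {
    if (k > 12) stop("exact mode capped at k = 12; use mode = \"montecarlo\"",
                     call. = FALSE)
    est <- aaf_exact(ev, k, factor_names = factors)
  } else {
    est <- aaf_montecarlo(ev, k, n_perms = n_perms, seed = seed,
                          factor_names = factors)
  }
  af_all <- ev(seq_len(k))
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  n_disabled <- sum(w[as.logical(data[[outcome]])])
  prevented <- expected_prevented(as.numeric(est), n_disabled,
                                  round_to = round_to)
  out <- tibble::tibble(
    factor = factors,
    aaf = as.numeric(est),
    rank = rank(-as.numeric(est), ties.method = "min"),
    prevented_raw = prevented$raw,
    prevented_rounded = prevented$rounded)
  structure(out, af_all = af_all, sum_aaf = sum(out$aaf),
            n_disabled = n_disabled, mode = mode, model = model,
            mc_se = attr(est, "mc_se"), n_perms = attr(est, "n_perms"),
            seed = seed)
}
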