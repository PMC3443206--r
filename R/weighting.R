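#' Fit a response-propensity model
#'
#' Logistic regression of the response indicator on the given predictors,
#' fitted on the full sample (respondents and non-respondents). Propensities
#' below the floor are clipped, with the number of clipped records recorded.
#'
#' @param sample Data frame containing `responded` plus the predictors.
#' @param predictors Character vector of predictor column names.
#' @param floor Lower bound applied to fitted propensities (default 0.02)
#'   to cap weight inflation.
#' @return Numeric vector of response propensities (one per row of
#'   `sample`), with attributes `"model"` (the `glm` fit) and `"n_clipped"`.
#' @export
fit_response_propensity <- function(sample, predictors, floor = 0.02) {
  if (!"responded" %in% names(sample)) {
    stop("`sample` must contain a `responded` column", call. = FALSE)
  }
  missing_pred <- setdiff(predictors, names(sample))
  if (length(missing_pred)) {
    stop("predictor(s) not in `sample`: ",
         paste(missing_pred, collapse = ", "), call. = FALSE)
  }
  if (all(sample$responded)) {
    return(structure(rep(1, nrow(sample)), model = NULL, n_clipped = 0L))
  }
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  form <- as.formula(paste("responded ~", rhs))
  fit <- suppressWarnings(glm(form, family = binomial(), data = sample))
  if (!fit$converged) {
    stop("response-propensity model did not converge", call. = FALSE)
  }
  cf <- coef(fit)
  bad <- names(cf)[is.na(cf) | abs(cf) > 15]
  if (length(bad)) {
    stop("separation or degenerate predictor in propensity model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  p <- predict(fit, type = "response")
  n_clipped <- sum(p < floor)
  if (n_clipped > 0) {
    warning(sprintf("%d propensities clipped at floor %.3g", n_clipped,
                    floor), call. = FALSE)
    p <- pmax(p, floor)
  }
  structure(as.numeric(p), model = fit, n_clipped = n_clipped)
}

#' Non-response weight adjustment
#'
#' Inverse-propensity adjustment: `design_weight / propensity`. Intended
#' for respondents only; non-respondents are dropped from the analysis
#' table downstream.
#'
#' @param design_weight Nonnegative design weights.
#' @param propensity Response propensities in (0, 1].
#' @param floor Propensities below this are clipped.
#' @return Adjusted weights.
#' @export
nonresponse_adjust <- function(design_weight, propensity, floor = 0.02) {
  if (any(propensity <= 0 | propensity > 1)) {
    stop("`propensity` must lie in (0,1]", call. = FALSE)
  }
  design_weight / pmax(propensity, floor)
}

#' Rake weights to marginal population totals
#'
#' Iterative proportional fitting: weights are multiplied within each
#' category of each margin variable in turn so weighted category totals
#' match their targets, cycling until the maximum relative margin error
#' falls below `tol`.
#'
#' @param weights Starting weights (nonnegative).
#' @param data Data frame holding the margin variables.
#' @param margins Tibble/data frame with columns `variable`, `category`,
#'   `target_total` (marginal totals per category of each variable).
#' @param tol Convergence tolerance on the maximum relative margin error.
#' @param max_iter Maximum raking cycles.
#' @return List with `weights`, `iterations`, `max_rel_error` and
#'   `converged`.
#' @export
calibrate_weights <- function(weights, data, margins, tol = 1e-8,
                              max_iter = 100) {
  margins$category <- as.character(margins$category)
  vars <- unique(margins$variable)
  targets <- lapply(vars, function(v) {
    m <- margins[margins$variable == v, ]
    setNames(m$target_total, m$category)
  })
  names(targets) <- vars
  if (any(unlist(targets) <= 0)) {
    stop("margin target totals must be positive", call. = FALSE)
  }
  cats <- lapply(vars, function(v) as.character(data[[v]]))
  names(cats) <- vars
  for (v in vars) {
    extra <- setdiff(unique(cats[[v]]), names(targets[[v]]))
    if (length(extra)) {
      stop(sprintf("margin for `%s` does not cover sample categor%s: %s",
                   v, if (length(extra) > 1) "ies" else "y",
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    empty <- names(targets[[v]])[!names(targets[[v]]) %in% cats[[v]]]
    if (length(empty)) {
      stop(sprintf("empty sample cell(s) with positive margin in `%s`: %s",
                   v, paste(empty, collapse = ", ")), call. = FALSE)
    }
  }
  w <- weights
  max_err <- function(w) {
    max(vapply(vars, function(v) {
      tot <- tapply(w, cats[[v]], sum)[names(targets[[v]])]
      max(abs(tot - targets[[v]]) / targets[[v]])
    }, numeric(1)))
  }
  err <- max_err(w)
  iter <- 0L
  while (err > tol && iter < max_iter) {
    for (v in vars) {
      tot <- tapply(w, cats[[v]], sum)
      ratio <- targets[[v]][names(tot)] / tot
      w <- w * ratio[cats[[v]]]
    }
    iter <- iter + 1L
    err <- max_err(w)
  }
  if (err > tol) {
    stop(sprintf(
      "raking did not converge in %d iterations (max relative margin error %.3g)",
      max_iter, err), call. = FALSE)
  }
  list(weights = as.numeric(w), iterations = iter, max_rel_error = err,
       converged = TRUE)
}

#' Build the full analysis weight chain
#'
#' Design weight times inverse response propensity, calibrated by raking to
#' the supplied margins; non-respondents are dropped after the propensity
#' fit, yielding the respondent-only analysis table.
#'
#' @param sample Sampled records with `design_weight` and `responded`.
#' @param predictors Propensity-model predictors (default: presumed
#'   severity, age, living situation).
#' @param margins Optional calibration margins (see [calibrate_weights()]);
#'   when `NULL` the calibrated weight equals the non-response-adjusted one.
#' @param floor Propensity floor.
#' @return Respondent tibble with `response_propensity`,
#'   `nonresponse_weight` and `calibrated_weight` columns; calibration
#'   diagnostics attached as attribute `"calibration"`.
#' @export
build_weights <- function(sample,
                          predictors = c("presumed_severity", "age",
                                         "living_alone"),
                          margins = NULL, floor = 0.02) {
  p <- fit_response_propensity(sample, predictors, floor = floor)
  sample$response_propensity <- as.numeric(p)
  respondents <- sample[sample$responded, , drop = FALSE]
  respondents$nonresponse_weight <-
    nonresponse_adjust(respondents$design_weight,
                       respondents$response_propensity, floor = floor)
  if (is.null(margins)) {
    respondents$calibrated_weight <- respondents$nonresponse_weight
    attr(respondents, "calibration") <- list(skipped = TRUE)
  } else {
    cal <- calibrate_weights(respondents$nonresponse_weight, respondents,
                             margins)
    respondents$calibrated_weight <- cal$weights
    attr(respondents, "calibration") <- cal[c("iterations", "max_rel_error",
                                              "converged")]
  }
  attr(respondents, "propensity_model") <- attr(p, "model")
  respondents
}
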