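microdata_required_columns <- function() {
  c("person_id", "stratum_id", "presumed_severity", "area_id",
    "sampling_fraction", "responded", "age", "sex", "marital_status",
    "living_alone", "education", "residence",
    paste0("adl_", 1:6), "self_report")
}

#' Extract analysis microdata from a survey table
#'
#' Selects the documented microdata schema columns (design fields,
#' covariates, `cond_*` indicators, the six ADL items and the self-report
#' answer) from a richer table such as the output of [draw_sample()] /
#' [apply_nonresponse()], dropping generator-internal columns.
#'
#' @param data Survey table.
#' @return Tibble in microdata schema order.
#' @export
as_microdata <- function(data) {
  cond_cols <- grep("^cond_", names(data), value = TRUE)
  keep <- c(microdata_required_columns(), "design_weight", cond_cols)
  missing_cols <- setdiff(setdiff(keep, "design_weight"), names(data))
  if (length(missing_cols)) {
    stop("microdata column(s) missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data[intersect(keep, names(data))]
}

validate_microdata <- function(md, lax = FALSE) {
  cond_cols <- grep("^cond_", names(md), value = TRUE)
  required <- microdata_required_columns()
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols)) {
    stop("microdata schema violation; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!length(cond_cols)) {
    stop("microdata schema violation: no `cond_*` indicator columns",
         call. = FALSE)
  }
  if (!lax) {
    known <- c(required, "design_weight", cond_cols)
    extra <- setdiff(names(md), known)
    if (length(extra)) {
      stop("unexpected microdata column(s) (use lax = TRUE to permit): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  adl <- as.matrix(md[paste0("adl_", 1:6)])
  if (anyNA(adl) || any(adl != round(adl)) || any(adl < 0 | adl > 4)) {
    stop("microdata schema violation: ADL items must be integers in 0..4",
         call. = FALSE)
  }
  invisible(md)
}

#' Configure an analysis run
#'
#' @param microdata Respondent-level microdata: a data frame or a CSV path
#'   following the documented schema (see [as_microdata()]).
#' @param margins Calibration margins: data frame or CSV with columns
#'   `variable`, `category`, `target_total`; `NULL` skips calibration.
#' @param definitions Disability definitions to analyze, a subset of
#'   `c("self_reported", "disabled", "severely_disabled")`.
#' @param by_age Analyze each broad age class in addition to the pooled
#'   population.
#' @param covariates Adjustment covariates for the AAF models; age class is
#'   added automatically for the pooled run.
#' @param propensity_predictors Predictors of the response-propensity
#'   model.
#' @param propensity_floor Lower clip for fitted response propensities.
#' @param af_threshold Gross-AF grouping threshold (proportion, default
#'   0.15).
#' @param aaf_mode `"exact"` or `"montecarlo"`.
#' @param n_perms Permutations for Monte Carlo AAF mode.
#' @param seed Master seed; every random stage of the run derives from it.
#' @param inclusive_forty Age-class boundary convention.
#' @param lax Permit extra microdata columns.
#' @return List of class `run_config`.
#' @export
run_config <- function(microdata, margins = NULL,
                       definitions = c("self_reported", "disabled",
                                       "severely_disabled"),
                       by_age = TRUE,
                       covariates = c("sex", "residence", "marital_status",
                                      "living_alone", "education"),
                       propensity_predictors = c("presumed_severity", "age",
                                                 "living_alone"),
                       propensity_floor = 0.02,
                       af_threshold = 0.15,
                       aaf_mode = c("exact", "montecarlo"),
                       n_perms = 2000, seed = 1L,
                       inclusive_forty = FALSE, lax = FALSE) {
  if (!length(definitions)) stop("`definitions` must be nonempty",
                                 call. = FALSE)
  definitions <- match.arg(definitions, several.ok = TRUE)
  if (af_threshold < 0 || af_threshold >= 1) {
    stop("`af_threshold` must lie in [0,1)", call. = FALSE)
  }
  structure(list(microdata = microdata, margins = margins,
                 definitions = definitions, by_age = by_age,
                 covariates = covariates,
                 propensity_predictors = propensity_predictors,
                 propensity_floor = propensity_floor,
                 af_threshold = af_threshold,
                 aaf_mode = match.arg(aaf_mode), n_perms = n_perms,
                 seed = as.integer(seed),
                 inclusive_forty = isTRUE(inclusive_forty),
                 lax = isTRUE(lax)),
            class = "run_config")
}

#' Run the full contribution-to-disability analysis
#'
#' Orchestrates the complete pipeline on respondent microdata: weighting
#' chain (propensity fit, non-response adjustment, raking when margins are
#' supplied), disability classification from the ADL items and the
#' self-report, weighted prevalence tables, gross attributable fractions
#' per condition and age class, grouping of low-AF conditions into "other
#' diseases", and covariate-adjusted average attributable fractions with
#' expected prevented-case counts, per disability definition and age class
#' (age-class runs refit the model within the class; the pooled run adds
#' age class as a covariate).
#'
#' @param config A [run_config()].
#' @return List of class `aaf_report`: `prevalence` (outcome and condition
#'   prevalences), `gross_af`, `grouping` (per definition), `aaf` (long
#'   tibble over definition x age class x factor with per-column `af_all`
#'   and `sum_aaf`), `weights` (respondent table with the weight chain) and
#'   `metadata`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  md <- config$microdata
  if (is.character(md)) md <- readr::read_csv(md, show_col_types = FALSE)
  md <- tibble::as_tibble(md)
  validate_microdata(md, lax = config$lax)
  margins <- config$margins
  if (is.character(margins)) {
    margins <- readr::read_csv(margins, show_col_types = FALSE)
  }
  conditions <- sub("^cond_", "", grep("^cond_", names(md), value = TRUE))

  if (!"design_weight" %in% names(md)) {
    md$design_weight <- 1 / md$sampling_fraction
  }
  status <- classify_disability(md[paste0("adl_", 1:6)], md$self_report)
  md$self_reported <- status$self_reported
  md$disabled <- status$disabled
  md$severely_disabled <- status$severely_disabled
  md$age_class <- assign_age_class(md$age, config$inclusive_forty)

  respondents <- build_weights(md, predictors = config$propensity_predictors,
                               margins = margins,
                               floor = config$propensity_floor)
  w_col <- "calibrated_weight"

  classes <- if (config$by_age) c(age_class_levels(), "total") else "total"
  class_rows <- function(cl) {
    if (cl == "total") seq_len(nrow(respondents))
    else which(respondents$age_class == cl)
  }

  prevalence <- purrr::map_dfr(classes, function(cl) {
    df <- respondents[class_rows(cl), ]
    dplyr::bind_rows(
      purrr::map_dfr(config$definitions, function(dn) {
        dplyr::mutate(
          weighted_prevalence(df[[dn]], df[[w_col]], strata = df$stratum_id),
          item = dn, type = "outcome", .before = 1)
      }),
      purrr::map_dfr(conditions, function(cn) {
        dplyr::mutate(
          weighted_prevalence(df[[paste0("cond_", cn)]], df[[w_col]],
                              strata = df$stratum_id),
          item = cn, type = "condition", .before = 1)
      })
    ) |> dplyr::mutate(age_class = cl, .before = 1)
  })

  gross <- purrr::map_dfr(config$definitions, function(dn) {
    purrr::map_dfr(classes, function(cl) {
      df <- respondents[class_rows(cl), ]
      gross_af(df, conditions, dn, weights = w_col) |>
        dplyr::mutate(definition = dn, age_class = cl, .before = 1)
    })
  })

  grouping <- lapply(config$definitions, function(dn) {
    per_class <- gross[gross$definition == dn & gross$age_class != "total", ]
    if (!nrow(per_class)) per_class <- gross[gross$definition == dn, ]
    group_low_af(per_class, threshold = config$af_threshold)
  })
  names(grouping) <- config$definitions

  aaf_tbl <- purrr::map_dfr(config$definitions, function(dn) {
    grp <- grouping[[dn]]
    df_all <- add_other_indicator(respondents, grp$other_members)
    purrr::map_dfr(classes, function(cl) {
      df <- df_all[class_rows(cl), ]
      covs <- config$covariates
      if (cl == "total" && config$by_age) covs <- c(covs, "age_class")
      res <- aaf(df, dn, grp$factor_set, covariates = covs,
                 weights = w_col, mode = config$aaf_mode,
                 n_perms = config$n_perms,
                 seed = child_seed(config$seed, 10 + match(cl, classes)))
      dplyr::mutate(res, definition = dn, age_class = cl,
                    af_all = attr(res, "af_all"),
                    sum_aaf = attr(res, "sum_aaf"),
                    n_disabled = attr(res, "n_disabled"), .before = 1)
    })
  })

  metadata <- list(
    seed = config$seed,
    definitions = config$definitions,
    conditions = conditions,
    covariates = config$covariates,
    af_threshold = config$af_threshold,
    aaf_mode = config$aaf_mode,
    grouping = lapply(grouping, function(g) g[c("kept", "other_members")]),
    calibration = attr(respondents, "calibration"),
    n_respondents = nrow(respondents),
    stage_hashes = list(prevalence = rlang::hash(prevalence),
                        gross_af = rlang::hash(gross),
                        aaf = rlang::hash(aaf_tbl))
  )
  structure(list(prevalence = prevalence, gross_af = gross,
                 grouping = grouping, aaf = aaf_tbl,
                 weights = respondents, metadata = metadata),
            class = "aaf_report")
}

#' @export
print.aaf_report <- function(x, ...) {
  cat("aafsurvey analysis report\n")
  cat(sprintf("  respondents: %d; definitions: %s\n",
              x$metadata$n_respondents,
              paste(x$metadata$definitions, collapse = ", ")))
  tot <- x$aaf[x$aaf$age_class == "total", ]
  for (dn in unique(tot$definition)) {
    td <- tot[tot$definition == dn, ]
    td <- td[order(td$rank), ]
    cat(sprintf("  %s: top factor %s (AAF %.1f%%), sum of AAFs %.1f%%\n",
                dn, td$factor[1], 100 * td$aaf[1], 100 * td$sum_aaf[1]))
  }
  invisible(x)
}
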