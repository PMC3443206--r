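#' Survey-weighted prevalence with Taylor-linearized confidence interval
#'
#' Estimates `sum(w x) / sum(w)` with a with-replacement Taylor
#' linearization variance, optionally stratified (the design strata are
#' treated as with-replacement sampling of units within strata).
#'
#' @param x Numeric/logical indicator vector.
#' @param w Nonnegative weights, not all zero.
#' @param strata Optional stratum identifiers for the variance.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `estimate`, `se`, `ci_low`, `ci_high`, `n`, `n_eff`
#'   (Kish effective sample size `(sum w)^2 / sum w^2`).
#' @export
weighted_prevalence <- function(x, w, strata = NULL, conf_level = 0.95) {
  if (all(w == 0)) stop("weights sum to zero", call. = FALSE)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  x <- as.numeric(x)
  W <- sum(w)
  est <- sum(w * x) / W
  z <- w * (x - est) / W
  strata <- if (is.null(strata)) rep(1L, length(x)) else strata
  v <- 0
  for (h in unique(strata)) {
    zh <- z[strata == h]
    nh <- length(zh)
    if (nh > 1) v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
  }
  se <- sqrt(v)
  q <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(estimate = est, se = se,
                 ci_low = max(0, est - q * se),
                 ci_high = min(1, est + q * se),
                 n = length(x), n_eff = W^2 / sum(w^2))
}

#' Crude weighted relative risk
#'
#' Weighted risk of the outcome among the exposed divided by the weighted
#' risk among the unexposed. Kept crude deliberately: Levin's formula
#' presumes the population relative risk, and covariate adjustment is the
#' job of the average-attributable-fraction stage.
#'
#' @param exposure,outcome Logical/0-1 vectors.
#' @param w Nonnegative weights.
#' @param continuity Add 0.5 to each weighted cell (rescued zero cells).
#' @return Tibble with `rr`, `risk_exposed`, `risk_unexposed` and the four
#'   weighted cell totals `a` (exposed cases), `b`, `c` (unexposed cases),
#'   `d`.
#' @export
estimate_rr <- function(exposure, outcome, w, continuity = FALSE) {
  exposure <- as.logical(exposure); outcome <- as.logical(outcome)
  a <- sum(w[exposure & outcome]); b <- sum(w[exposure & !outcome])
  c_ <- sum(w[!exposure & outcome]); d <- sum(w[!exposure & !outcome])
  if (continuity) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  if (a + b == 0 || c_ + d == 0) {
    stop("both exposure groups must have positive weighted size",
         call. = FALSE)
  }
  if (c_ == 0) {
    stop("zero weighted risk among the unexposed: relative risk undefined ",
         "(consider `continuity = TRUE`)", call. = FALSE)
  }
  r1 <- a / (a + b); r0 <- c_ / (c_ + d)
  tibble::tibble(rr = r1 / r0, risk_exposed = r1, risk_unexposed = r0,
                 a = a, b = b, c = c_, d = d)
}

#' Levin's attributable fraction
#'
#' `AF = Pe (RR - 1) / (1 + Pe (RR - 1))`: the fraction of the overall
#' outcome rate that would be avoided if the exposure were eliminated,
#' from exposure prevalence `Pe` and relative risk `RR`.
#'
#' @param pe Exposure prevalence in `[0, 1]`.
#' @param rr Relative risk (> 0). Values below 1 give a negative AF.
#' @return Attributable fraction (vectorized).
#' @export
levin_af <- function(pe, rr) {
  if (any(pe < 0 | pe > 1)) stop("`pe` must lie in [0,1]", call. = FALSE)
  if (any(rr <= 0)) stop("`rr` must be positive", call. = FALSE)
  x <- pe * (rr - 1)
  if (any(1 + x <= 0)) stop("degenerate AF denominator", call. = FALSE)
  x / (1 + x)
}

#' Log-complement confidence interval for an attributable fraction
#'
#' Delta-method interval on `log(1 - AF)` from the cross-sectional 2x2
#' table of exposure by outcome. With weighted data the cells should be
#' effective counts: weighted cells rescaled so their total equals the
#' Kish effective sample size (see [af_cells_effective()]); the count-based
#' variance formula assumes unweighted multinomial sampling.
#'
#' @param a,b,c,d Cell counts: exposed cases, exposed non-cases, unexposed
#'   cases, unexposed non-cases. All four must be positive.
#' @param conf_level Confidence level.
#' @param continuity Add 0.5 to each cell first.
#' @return Tibble with `af`, `ci_low`, `ci_high`, `se_log_complement`.
#' @export
fleiss_ci <- function(a, b, c, d, conf_level = 0.95, continuity = FALSE) {
  a <- unname(a); b <- unname(b); c <- unname(c); d <- unname(d)
  if (continuity) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  if (min(a, b, c, d) <= 0) {
    stop("all four cells must be positive (consider `continuity = TRUE`)",
         call. = FALSE)
  }
  n <- a + b + c + d
  # 1 - AF = [c/(c+d)] / [(a+c)/n]; delta method on log(1-AF) with the
  # cells treated as independent Poisson (multinomial-equivalent gradients)
  af <- 1 - (c / (c + d)) / ((a + c) / n)
  ga <- 1 / n - 1 / (a + c)
  gb <- 1 / n
  gc <- 1 / c + 1 / n - 1 / (c + d) - 1 / (a + c)
  gd <- 1 / n - 1 / (c + d)
  se <- sqrt(a * ga^2 + b * gb^2 + c * gc^2 + d * gd^2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(af = af,
                 ci_low = 1 - (1 - af) * exp(z * se),
                 ci_high = 1 - (1 - af) * exp(-z * se),
                 se_log_complement = se)
}

#' Effective 2x2 cells for weighted interval estimation
#'
#' Rescales the weighted exposure-by-outcome cell totals so that they sum
#' to the Kish effective sample size `(sum w)^2 / sum w^2`, the unweighted
#' equivalent n of the weighted sample.
#'
#' @inheritParams estimate_rr
#' @return Tibble with effective cells `a`, `b`, `c`, `d` and `n_eff`.
#' @export
af_cells_effective <- function(exposure, outcome, w) {
  exposure <- as.logical(exposure); outcome <- as.logical(outcome)
  n_eff <- sum(w)^2 / sum(w^2)
  scale <- n_eff / sum(w)
  tibble::tibble(
    a = sum(w[exposure & outcome]) * scale,
    b = sum(w[exposure & !outcome]) * scale,
    c = sum(w[!exposure & outcome]) * scale,
    d = sum(w[!exposure & !outcome]) * scale,
    n_eff = n_eff)
}

#' Gross attributable fractions for a set of conditions
#'
#' One-stop computation per condition: weighted prevalence, crude weighted
#' relative risk, Levin AF and its log-complement confidence interval on
#' effective counts.
#'
#' @param data Respondent table with condition indicator columns.
#' @param conditions Condition names (indicator columns `cond_<name>`, or
#'   bare column names if present).
#' @param outcome Name of the logical outcome column.
#' @param weights Name of the weight column.
#' @param conf_level Confidence level for the AF interval.
#' @return Tibble, one row per condition: `condition`, `pe`, `rr`, `af`,
#'   `ci_low`, `ci_high`.
#' @export
gross_af <- function(data, conditions, outcome, weights = "calibrated_weight",
                     conf_level = 0.95) {
  w <- data[[weights]]
  y <- as.logical(data[[outcome]])
  purrr::map_dfr(conditions, function(cn) {
    col <- if (cn %in% names(data)) cn else paste0("cond_", cn)
    x <- as.logical(data[[col]])
    pe <- sum(w * x) / sum(w)
    rr <- estimate_rr(x, y, w)$rr
    cells <- af_cells_effective(x, y, w)
    ci <- fleiss_ci(cells$a, cells$b, cells$c, cells$d,
                    conf_level = conf_level)
    tibble::tibble(condition = cn, pe = pe, rr = rr, af = levin_af(pe, rr),
                   ci_low = ci$ci_low, ci_high = ci$ci_high)
  })
}

#' Merge conditions with low attributable fractions
#'
#' Conditions whose gross AF is at or below the threshold in every age
#' class (default rule; `scope = "per_class"` applies the rule class by
#' class) are merged into a single `"other_diseases"` indicator, the
#' logical OR of the member conditions per record.
#'
#' @param af_results Tibble from [gross_af()], optionally with an
#'   `age_class` column when the rule is evaluated over several classes.
#' @param threshold AF threshold as a proportion (default 0.15); ties are
#'   grouped.
#' @param scope `"all_classes"` (merged iff low in every class) or
#'   `"per_class"`.
#' @return List with `kept` (conditions analyzed on their own),
#'   `other_members` (merged conditions) and `factor_set` (kept plus
#'   `"other_diseases"` when any condition was merged).
#' @export
group_low_af <- function(af_results, threshold = 0.15,
                         scope = c("all_classes", "per_class")) {
  scope <- match.arg(scope)
  by_cond <- af_results |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(max_af = max(.data$af), .groups = "drop")
  low <- by_cond$condition[by_cond$max_af <= threshold]
  kept <- setdiff(unique(af_results$condition), low)
  if (!length(kept)) {
    stop("every condition falls at or below the AF threshold; ",
         "nothing to analyze", call. = FALSE)
  }
  factor_set <- if (length(low)) c(kept, "other_diseases") else kept
  list(kept = kept, other_members = low, factor_set = factor_set,
       threshold = threshold, scope = scope)
}

#' Add the merged "other diseases" indicator to a respondent table
#'
#' @param data Respondent table with `cond_<name>` columns.
#' @param members Conditions merged into the group.
#' @return `data` with a `cond_other_diseases` column (OR over members).
#' @export
add_other_indicator <- function(data, members) {
  if (!length(members)) return(data)
  cols <- paste0("cond_", members)
  data$cond_other_diseases <- as.integer(rowSums(data[cols]) > 0)
  data
}
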