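#' Classify disability from ADL items and self-report
#'
#' Applies the three disability definitions to the six Katz ADL items
#' (bathing, dressing, toileting, transferring, meal preparation,
#' self-feeding; each scored 0 = no difficulty to 4 = inability to do it
#' alone) and the self-report answer:
#' * `disabled` — any restriction: at least one item score >= 1;
#' * `severely_disabled` — inability to perform at least one ADL alone:
#'   at least one item score = 4;
#' * `self_reported` — affirmative answer to the disability question.
#'
#' @param adl Matrix or data frame with six integer columns scored 0-4.
#' @param self_report Logical vector of self-report answers.
#' @param missing Policy for missing item scores: `"error"` (default) or
#'   `"zero"` (available-case: treat missing as 0, reporting the count via
#'   `message()`).
#' @return Tibble with logical columns `self_reported`, `disabled`,
#'   `severely_disabled`. Severe disability always implies disability.
#' @export
classify_disability <- function(adl, self_report,
                                missing = c("error", "zero")) {
  missing <- match.arg(missing)
  adl <- as.matrix(adl)
  if (ncol(adl) != 6) stop("`adl` must have exactly six items", call. = FALSE)
  if (anyNA(adl)) {
    if (missing == "error") {
      stop("missing ADL item scores (set missing = \"zero\" for ",
           "available-case classification)", call. = FALSE)
    }
    n_miss <- sum(is.na(adl))
    message(sprintf("%d missing ADL item scores treated as 0", n_miss))
    adl[is.na(adl)] <- 0
  }
  if (any(adl != round(adl)) || any(adl < 0 | adl > 4)) {
    stop("ADL item scores must be integers in 0..4", call. = FALSE)
  }
  if (length(self_report) != nrow(adl)) {
    stop("`self_report` length must match rows of `adl`", call. = FALSE)
  }
  tibble::tibble(
    self_reported = as.logical(self_report),
    disabled = rowSums(adl >= 1) > 0,
    severely_disabled = rowSums(adl == 4) > 0
  )
}

#' The bundled condition-code mapping table
#'
#' Maps each checklist disease code to its chronic-condition group, with
#' flags for symptom codes exempt from the physician-diagnosis rule and for
#' codes subject to the treated-in-the-last-year rule. Shipped as an
#' editable CSV resource.
#'
#' @return Tibble with columns `code`, `label`, `group`, `symptom_exempt`,
#'   `treatment_rule_applies`.
#' @export
condition_code_table <- function() {
  path <- system.file("extdata", "condition_codes.csv",
                      package = "aafsurvey", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Map a raw disease checklist to condition-group indicators
#'
#' A reported disease qualifies only if it was physician-diagnosed (symptom
#' codes such as back pain, neck pain and headache are exempt), was treated
#' during the previous year when the treatment rule applies to the code,
#' and is not a stroke without sequelae. Each condition-group indicator is
#' the OR over its qualifying member diseases. Obesity is derived from
#' height and weight as BMI >= 30 kg/m^2 and feeds the endocrine group.
#'
#' @param checklist Data frame with columns `person_id`, `code`,
#'   `physician_diagnosed`, `treated_last_year` and (optionally)
#'   `stroke_without_sequelae`.
#' @param persons Optional data frame with `person_id`, `height_m`,
#'   `weight_kg` used for the obesity derivation; persons listed here but
#'   absent from the checklist still get a (possibly all-FALSE) row.
#' @param mapping Code mapping table; defaults to the bundled
#'   [condition_code_table()].
#' @return Tibble with `person_id` and one logical column per condition
#'   group present in `mapping`.
#' @export
map_conditions <- function(checklist, persons = NULL,
                           mapping = condition_code_table()) {
  unknown <- setdiff(unique(checklist$code), mapping$code)
  if (length(unknown)) {
    stop("unknown checklist code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!"stroke_without_sequelae" %in% names(checklist)) {
    checklist$stroke_without_sequelae <- FALSE
  }
  cl <- dplyr::left_join(checklist, mapping, by = "code")
  cl$qualifies <-
    (cl$physician_diagnosed | cl$symptom_exempt) &
    (cl$treated_last_year | !cl$treatment_rule_applies) &
    !(cl$code == "stroke" & cl$stroke_without_sequelae %in% TRUE)

  ids <- unique(c(checklist$person_id, persons$person_id))
  groups <- unique(mapping$group)
  out <- tibble::tibble(person_id = ids)
  agg <- cl |>
    dplyr::filter(.data$qualifies) |>
    dplyr::distinct(.data$person_id, .data$group) |>
    dplyr::mutate(value = TRUE) |>
    tidyr::pivot_wider(names_from = "group", values_from = "value",
                       values_fill = FALSE)
  out <- dplyr::left_join(out, agg, by = "person_id")
  for (g in groups) {
    if (!g %in% names(out)) out[[g]] <- FALSE
    out[[g]][is.na(out[[g]])] <- FALSE
  }
  if (!is.null(persons) &&
      all(c("height_m", "weight_kg") %in% names(persons))) {
    bmi <- persons$weight_kg / persons$height_m^2
    obese <- tibble::tibble(person_id = persons$person_id, bmi = bmi)
    n_missing <- sum(is.na(bmi))
    if (n_missing > 0) {
      message(sprintf(
        "%d person(s) missing height or weight; obesity not derived",
        n_missing))
    }
    out <- dplyr::left_join(out, obese, by = "person_id")
    out$endocrine <- out$endocrine | (!is.na(out$bmi) & out$bmi >= 30)
    out$bmi <- NULL
  }
  out[c("person_id", groups)]
}
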