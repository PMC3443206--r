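#' Published national AAF estimates (Disability-Health Survey 2008-2009)
#'
#' The published average-attributable-fraction tables of the 2008-2009
#' French Disability-Health Survey analysis: AAF (percent, one decimal) per
#' chronic condition for each disability definition and age class, with the
#' estimated number of disabled persons per column and the printed column
#' sum. Bundled so that arithmetic-consistency checks and worked examples
#' can recompute derived quantities (prevented-case counts, column sums)
#' from the published inputs.
#'
#' @return Tibble with columns `definition` (`disabled`,
#'   `severely_disabled`, `self_reported`), `age_class` (`18-40`, `40-65`,
#'   `>65`, `total`), `condition`, `aaf_pct`, `n_disabled` (per-column
#'   estimated disabled population) and `printed_sum` (the published column
#'   sum in percent).
#' @export
dhs_reference_aaf <- function() {
  row <- function(definition, age_class, n, printed_sum, conditions, aafs) {
    tibble::tibble(definition = definition, age_class = age_class,
                   condition = conditions, aaf_pct = aafs,
                   n_disabled = n, printed_sum = printed_sum)
  }
  dplyr::bind_rows(
    # ADL disability
    row("disabled", "18-40", 143859, 86.6,
        c("psychiatric", "musculoskeletal", "neurological", "sensorial",
          "urological", "sequelae_of_injury", "cardiovascular", "endocrine",
          "other_diseases"),
        c(27.4, 17.6, 11.0, 10.0, 8.7, 7.6, 2.8, 1.4, 0.1)),
    row("disabled", "40-65", 534675, 79.7,
        c("musculoskeletal", "endocrine", "neurological", "psychiatric",
          "cardiovascular", "sequelae_of_injury", "sensorial", "urological",
          "other_diseases"),
        c(20.9, 13.6, 13.3, 10.2, 7.1, 6.1, 4.8, 2.0, 1.7)),
    row("disabled", ">65", 1158219, 67.6,
        c("neurological", "cardiovascular", "musculoskeletal", "urological",
          "other_diseases", "endocrine", "sequelae_of_injury", "psychiatric",
          "sensorial"),
        c(21.0, 12.4, 10.9, 10.3, 5.5, 5.2, 1.4, 0.9, 0.0)),
    row("disabled", "total", 1836753, 75.3,
        c("neurological", "musculoskeletal", "cardiovascular", "endocrine",
          "urological", "psychiatric", "sensorial", "sequelae_of_injury",
          "other_diseases"),
        c(17.4, 16.4, 11.1, 8.2, 7.4, 5.8, 3.8, 3.1, 3.3)),
    # severe disability
    row("severely_disabled", "18-40", 67681, 94.5,
        c("psychiatric", "neurological", "urological", "sequelae_of_injury",
          "musculoskeletal", "sensorial", "cardiovascular", "endocrine",
          "other_diseases"),
        c(40.3, 16.0, 15.4, 12.5, 3.7, 3.5, 3.1, 0.0, 0.0)),
    row("severely_disabled", "40-65", 112254, 85.0,
        c("neurological", "endocrine", "psychiatric", "urological",
          "other_diseases", "sequelae_of_injury", "cardiovascular",
          "sensorial", "musculoskeletal"),
        c(29.7, 15.4, 14.6, 7.6, 7.4, 7.0, 3.1, 0.2, 0.0)),
    row("severely_disabled", ">65", 493264, 74.1,
        c("neurological", "urological", "cardiovascular", "other_diseases",
          "endocrine", "psychiatric", "sequelae_of_injury",
          "musculoskeletal", "sensorial"),
        c(33.6, 19.9, 12.4, 4.2, 1.7, 1.6, 0.7, 0.0, 0.0)),
    row("severely_disabled", "total", 673199, 74.1,
        c("neurological", "urological", "cardiovascular", "psychiatric",
          "endocrine", "sequelae_of_injury", "other_diseases",
          "musculoskeletal", "sensorial"),
        c(31.0, 17.5, 9.7, 7.6, 3.4, 3.2, 1.7, 0.0, 0.0)),
    # self-reported disability
    row("self_reported", "18-40", 804615, 78.4,
        c("psychiatric", "sensorial", "musculoskeletal", "endocrine",
          "sequelae_of_injury", "cardiovascular", "neurological",
          "other_diseases", "urological"),
        c(23.8, 17.5, 13.5, 6.6, 6.2, 3.5, 3.5, 3.3, 0.5)),
    row("self_reported", "40-65", 2440944, 81.5,
        c("musculoskeletal", "psychiatric", "sensorial", "endocrine",
          "other_diseases", "cardiovascular", "neurological",
          "sequelae_of_injury", "urological"),
        c(15.8, 13.1, 10.2, 10.0, 7.2, 6.9, 6.5, 5.9, 5.9)),
    row("self_reported", ">65", 2473309, 60.5,
        c("musculoskeletal", "cardiovascular", "neurological", "endocrine",
          "urological", "other_diseases", "sensorial", "psychiatric",
          "sequelae_of_injury"),
        c(13.6, 11.9, 9.3, 6.1, 5.7, 5.4, 5.2, 3.0, 0.3)),
    row("self_reported", "total", 5718868, 73.4,
        c("musculoskeletal", "sensorial", "psychiatric", "cardiovascular",
          "endocrine", "neurological", "other_diseases",
          "sequelae_of_injury", "urological"),
        c(15.4, 13.2, 9.7, 8.5, 8.0, 7.0, 5.5, 3.7, 2.4))
  )
}

#' Published population counts (Disability-Health Survey 2008-2009)
#'
#' Estimated population totals and per-condition counts of the published
#' analysis: the adult household population, the population with at least
#' one chronic condition, and for each condition group the estimated number
#' of persons together with the published prevalence percentages (among
#' persons with chronic conditions and among all adults).
#'
#' @return List with `adult_population`, `chronic_population` and a tibble
#'   `conditions` (`condition`, `n_survey`, `n_estimated`,
#'   `prev_chronic_pct`, `prev_overall_pct`).
#' @export
dhs_reference_counts <- function() {
  list(
    adult_population = 47524123,
    chronic_population = 38837743,
    conditions = tibble::tribble(
      ~condition, ~n_survey, ~n_estimated, ~prev_chronic_pct, ~prev_overall_pct,
      "cancer", 922, 923096, 2.4, 1.9,
      "cardiovascular", 8385, 10095211, 26.0, 21.2,
      "dermatological", 1780, 2957850, 7.6, 6.2,
      "digestive", 1966, 2179675, 5.6, 4.6,
      "endocrine", 7071, 8932739, 23.0, 18.8,
      "musculoskeletal", 10648, 13656107, 35.2, 28.7,
      "neurological", 4144, 4796960, 12.4, 10.1,
      "psychiatric", 3371, 2983786, 7.7, 6.3,
      "respiratory", 3668, 5443578, 14.0, 11.5,
      "sensorial", 18447, 31098284, 80.1, 65.4,
      "sequelae_of_injury", 1511, 1683703, 4.3, 3.5,
      "urological", 2147, 2289618, 5.9, 4.8)
  )
}
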