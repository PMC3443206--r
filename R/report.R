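format_pct <- function(x) sprintf("%.1f", 100 * x)

#' Write an analysis report bundle to disk
#'
#' Writes one CSV per table (prevalence, gross AF, AAF per definition) plus
#' a JSON metadata file. Percentages are formatted to one decimal with the
#' unrounded value retained in a `_raw` column. Each AAF table gains a sums
#' row per (definition, age class) column: by default the sum of unrounded
#' AAFs, formatted once at the end; `sum_mode = "sum_of_rounded"` instead
#' sums the formatted one-decimal entries.
#'
#' @param bundle An `aaf_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @param sum_mode `"raw"` (default) or `"sum_of_rounded"`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir, sum_mode = c("raw", "sum_of_rounded")) {
  sum_mode <- match.arg(sum_mode)
  stopifnot(inherits(bundle, "aaf_report"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  paths <- character(0)

  prev <- bundle$prevalence |>
    dplyr::mutate(estimate_pct = format_pct(.data$estimate)) |>
    dplyr::rename(estimate_raw = "estimate")
  p <- file.path(dir, "prevalence.csv")
  readr::write_csv(prev, p); paths <- c(paths, p)

  gross <- bundle$gross_af |>
    dplyr::mutate(af_pct = format_pct(.data$af)) |>
    dplyr::rename(af_raw = "af")
  p <- file.path(dir, "gross_af.csv")
  readr::write_csv(gross, p); paths <- c(paths, p)

  for (dn in unique(bundle$aaf$definition)) {
    tab <- bundle$aaf[bundle$aaf$definition == dn, ]
    out <- purrr::map_dfr(unique(tab$age_class), function(cl) {
      tc <- tab[tab$age_class == cl, ]
      tc <- tc[order(tc$rank), ]
      body <- tibble::tibble(
        definition = dn, age_class = cl, rank = tc$rank, factor = tc$factor,
        aaf_raw = tc$aaf, aaf_pct = format_pct(tc$aaf),
        prevented_raw = tc$prevented_raw,
        prevented_rounded = tc$prevented_rounded,
        af_all_raw = tc$af_all, n_disabled = tc$n_disabled)
      sum_pct <- if (sum_mode == "raw") format_pct(sum(tc$aaf))
                 else sprintf("%.1f", sum(as.numeric(body$aaf_pct)))
      sums <- tibble::tibble(
        definition = dn, age_class = cl, rank = NA_integer_,
        factor = "(sum)", aaf_raw = sum(tc$aaf), aaf_pct = sum_pct,
        prevented_raw = sum(tc$prevented_raw),
        prevented_rounded = NA_real_,
        af_all_raw = tc$af_all[1], n_disabled = tc$n_disabled[1])
      dplyr::bind_rows(body, sums)
    })
    p <- file.path(dir, paste0("aaf_", dn, ".csv"))
    readr::write_csv(out, p); paths <- c(paths, p)
  }

  p <- file.path(dir, "metadata.json")
  jsonlite::write_json(bundle$metadata, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
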