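# Cohort aggregation and technique-vs-technique comparison.

# canonical display order for metrics in reports
metric_display_order <- function(metrics) {
  canonical <- c("D99%", "D30%", "D50%", "D5%", "V35Gy", "V17Gy",
                 "Dmean", "Dmax", "MU", "TCP", "NTCP")
  extra <- sort(setdiff(unique(metrics), canonical))
  factor(metrics, levels = c(canonical, extra))
}

#' Percent change relative to a reference value
#'
#' `100 * (other - reference) / reference`: negative means `other` is lower
#' than the reference. In technique comparisons the single-arc plan is
#' always the reference.
#'
#' @param reference Reference value(s), nonzero.
#' @param other Comparison value(s).
#' @return Percent change, vectorised.
#' @examples
#' percent_change(34.7, 28.5)  # -17.9, i.e. 18% lower
#' @export
percent_change <- function(reference, other) {
  if (any(reference == 0)) abort_validation("Reference value must be nonzero.")
  100 * (other - reference) / reference
}

#' Cohort summary of per-plan metrics
#'
#' Takes tidy plan records - one row per (patient, technique, structure,
#' metric) - and returns the per-technique mean and sample standard
#' deviation (n - 1) of each metric. Every patient present in the records
#' must carry every summarised metric; missing values are an error naming
#' the patients, never a silent drop.
#'
#' @param records A data frame with columns `patient_id`, `technique`,
#'   `structure`, `metric`, `value`.
#' @param metrics Optional character vector restricting which metric labels
#'   are summarised.
#' @return A tibble with `technique`, `structure`, `metric`, `n`, `mean`,
#'   `sd` (`sd` is `NA` for a single plan).
#' @export
cohort_summary <- function(records, metrics = NULL) {
  records <- validate_records(records)
  if (!is.null(metrics)) {
    records <- dplyr::filter(records, .data$metric %in% metrics)
    if (!nrow(records)) abort_validation("No records match the requested metrics.")
  }
  patients <- unique(records$patient_id)
  complete <- records |>
    dplyr::group_by(.data$technique, .data$structure, .data$metric) |>
    dplyr::summarise(missing = list(setdiff(patients, .data$patient_id)),
                     .groups = "drop") |>
    dplyr::filter(lengths(.data$missing) > 0)
  if (nrow(complete)) {
    abort_validation(
      "Metric %s (%s, %s) is missing for patient(s) %s.",
      complete$metric[1], complete$structure[1], complete$technique[1],
      paste(complete$missing[[1]], collapse = ", "))
  }
  records |>
    dplyr::group_by(.data$technique, .data$structure, .data$metric) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$technique, .data$structure,
                   metric_display_order(.data$metric))
}

validate_records <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("patient_id", "technique", "structure", "metric", "value")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort_validation("Plan records lack column(s): %s.", paste(miss, collapse = ", "))
  }
  if (!nrow(records)) abort_validation("Plan records are empty.")
  dup <- records |>
    dplyr::count(.data$patient_id, .data$technique, .data$structure, .data$metric) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort_validation("Duplicate metric %s for %s/%s/%s.",
                     dup$metric[1], dup$patient_id[1], dup$technique[1], dup$structure[1])
  }
  records
}

#' Compare two delivery techniques across a patient cohort
#'
#' Builds the full comparison report from tidy plan records: per-technique
#' cohort means and sample SDs of every metric, and the percent change of
#' the comparison-technique cohort mean relative to the reference cohort
#' mean (ratio of means, the convention that matches how planning studies
#' quote "on average X% lower"). Every patient must appear under both
#' techniques; unpaired patients are an error naming them.
#'
#' @param records Tidy plan records (see [cohort_summary()]).
#' @param reference,comparison Technique labels; by default the reference
#'   is `"single-arc"` and the comparison the remaining technique.
#' @return A `cohort_report`: use [generics::tidy()] for the per-metric
#'   table and [generics::glance()] for the one-row overview.
#' @export
compare_techniques <- function(records, reference = "single-arc", comparison = NULL) {
  records <- validate_records(records)
  techs <- unique(records$technique)
  if (!reference %in% techs) {
    abort_validation("Reference technique '%s' not present (have: %s).",
                     reference, paste(techs, collapse = ", "))
  }
  comparison <- comparison %||% setdiff(techs, reference)[1]
  if (is.na(comparison) || !comparison %in% techs) {
    abort_validation("Comparison technique not found in the records.")
  }
  pair <- records |>
    dplyr::filter(.data$technique %in% c(reference, comparison)) |>
    dplyr::distinct(.data$patient_id, .data$technique)
  unpaired <- pair |>
    dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n < 2)
  if (nrow(unpaired)) {
    abort_validation("Patient(s) without both techniques: %s.",
                     paste(unpaired$patient_id, collapse = ", "))
  }
  summ <- cohort_summary(
    dplyr::filter(records, .data$technique %in% c(reference, comparison)))
  wide <- summ |>
    dplyr::mutate(side = ifelse(.data$technique == reference, "ref", "cmp")) |>
    tidyr::pivot_wider(
      id_cols = c("structure", "metric"),
      names_from = "side",
      values_from = c("mean", "sd", "n"),
      names_glue = "{.value}_{side}") |>
    dplyr::mutate(percent_change = ifelse(
      .data$mean_ref != 0,
      percent_change(.data$mean_ref, .data$mean_cmp),
      NA_real_)) |>
    dplyr::arrange(.data$structure, metric_display_order(.data$metric)) |>
    dplyr::select("structure", "metric", "mean_ref", "sd_ref",
                  "mean_cmp", "sd_cmp", "percent_change")
  structure(
    list(summary = wide, reference = reference, comparison = comparison,
         n_patients = length(unique(pair$patient_id))),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %s vs %s (reference), %d patients\n",
              x$comparison, x$reference, x$n_patients))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @method tidy cohort_report
#' @export
tidy.cohort_report <- function(x, ...) x$summary

#' @method glance cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  tibble::tibble(reference = x$reference, comparison = x$comparison,
                 n_patients = x$n_patients, n_metrics = nrow(x$summary))
}

#' Render or re-load a cohort comparison report
#'
#' `render_report()` serialises a [compare_techniques()] report. The text
#' format rounds doses and percentages to one decimal (monitor units to
#' integers) for human reading; `csv` and `json` keep full precision, and
#' a JSON document re-loaded with `parse_report_json()` reproduces the
#' report exactly. Ordering is deterministic: structures alphabetical,
#' metrics in the clinical display order.
#'
#' @param report A `cohort_report`.
#' @param format `"text"`, `"csv"` or `"json"`.
#' @param path Optional output file; when `NULL` the document is returned
#'   as a character string.
#' @return The rendered document (invisibly, when written to `path`).
#' @export
render_report <- function(report, format = c("text", "csv", "json"), path = NULL) {
  stopifnot(inherits(report, "cohort_report"))
  format <- match.arg(format)
  if (!nrow(report$summary)) abort_validation("Refusing to render an empty report.")
  doc <- switch(format,
    text = render_report_text(report),
    csv = {
      con <- textConnection("csv_out", "w", local = TRUE)
      utils::write.csv(report$summary, con, row.names = FALSE)
      close(con)
      paste(csv_out, collapse = "\n")
    },
    json = jsonlite::toJSON(
      list(reference = report$reference, comparison = report$comparison,
           n_patients = report$n_patients, summary = report$summary),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null",
      pretty = TRUE)
  )
  if (is.null(path)) return(doc)
  writeLines(as.character(doc), path)
  invisible(doc)
}

render_report_text <- function(report) {
  fmt1 <- function(metric, v) {
    ifelse(is.na(v), "-",
           ifelse(metric == "MU", sprintf("%.0f", v), sprintf("%.1f", v)))
  }
  s <- report$summary
  body <- sprintf("%-18s %-7s %10s %8s %12s %8s %9s",
                  s$structure, s$metric,
                  fmt1(s$metric, s$mean_ref), fmt1(s$metric, s$sd_ref),
                  fmt1(s$metric, s$mean_cmp), fmt1(s$metric, s$sd_cmp),
                  ifelse(is.na(s$percent_change), "-",
                         sprintf("%+.1f%%", s$percent_change)))
  head <- sprintf("%-18s %-7s %10s %8s %12s %8s %9s",
                  "structure", "metric",
                  paste0("mean(", substr(report$reference, 1, 4), ")"), "sd",
                  paste0("mean(", substr(report$comparison, 1, 4), ")"), "sd",
                  "change")
  paste(c(sprintf("Technique comparison: %s vs %s (reference), n = %d",
                  report$comparison, report$reference, report$n_patients),
          head, body), collapse = "\n")
}

#' @rdname render_report
#' @param json A JSON string or file path produced by
#'   `render_report(format = "json")`.
#' @export
parse_report_json <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  summary <- tibble::as_tibble(raw$summary)
  for (col in c("mean_ref", "sd_ref", "mean_cmp", "sd_cmp", "percent_change")) {
    summary[[col]] <- as.numeric(summary[[col]])
  }
  structure(
    list(summary = summary, reference = raw$reference,
         comparison = raw$comparison, n_patients = raw$n_patients),
    class = "cohort_report")
}

#' Percent change between cohort means
#'
#' Convenience for comparing a summary table of cohort means directly
#' (e.g. the bundled [prostate_vmat_summary()] fixture) without per-patient
#' records: for each (structure, metric), the percent change of the
#' comparison technique's mean relative to the reference technique's mean.
#'
#' @param means A data frame with columns `technique`, `structure`,
#'   `metric`, `mean`.
#' @inheritParams compare_techniques
#' @return A tibble with `structure`, `metric`, `mean_ref`, `mean_cmp`,
#'   `percent_change`.
#' @examples
#' percent_change_summary(prostate_vmat_summary())
#' @export
percent_change_summary <- function(means, reference = "single-arc", comparison = NULL) {
  means <- tibble::as_tibble(means)
  need <- c("technique", "structure", "metric", "mean")
  if (!all(need %in% names(means))) {
    abort_validation("Means table needs columns %s.", paste(need, collapse = ", "))
  }
  techs <- unique(means$technique)
  comparison <- comparison %||% setdiff(techs, reference)[1]
  means |>
    dplyr::filter(.data$technique %in% c(reference, comparison)) |>
    dplyr::mutate(side = ifelse(.data$technique == reference, "ref", "cmp")) |>
    tidyr::pivot_wider(
      id_cols = c("structure", "metric"),
      names_from = "side", values_from = "mean",
      names_glue = "mean_{side}") |>
    dplyr::mutate(percent_change = percent_change(.data$mean_ref, .data$mean_cmp)) |>
    dplyr::arrange(.data$structure, metric_display_order(.data$metric))
}
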