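#' Default metric sheet per structure
#'
#' Which metrics are reported for which structure: target coverage (D99%)
#' for the PTV, the rectum/bladder dose-volume criteria (D30%, D50%,
#' V17Gy, V35Gy), femoral-head D5%, and mean/maximum dose everywhere.
#' Structures not listed fall back to mean and maximum dose.
#'
#' @return A tibble with columns `structure`, `metric`.
#' @export
default_metric_sheet <- function() {
  tibble::tibble(
    structure = c(
      rep("PTV", 3), rep("CTV", 2),
      rep(c("Rectum", "Bladder"), each = 6),
      rep(c("LeftFemoralHead", "RightFemoralHead"), each = 3)
    ),
    metric = c(
      "D99%", "Dmean", "Dmax", "Dmean", "Dmax",
      rep(c("D30%", "D50%", "V17Gy", "V35Gy", "Dmean", "Dmax"), 2),
      rep(c("D5%", "Dmean", "Dmax"), 2)
    )
  )
}

# Normalise the three accepted plan-set inputs (a dvh_cohort, a manifest
# path, or a manifest tibble) into a tibble of loaded DVHs.
load_plan_set <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !inherits(x, "dvh_cohort") &&
      all(c("dvhs", "plans") %in% names(x))) {
    return(x)  # already loaded
  }
  if (inherits(x, "dvh_cohort")) {
    return(list(dvhs = x$dvhs[, c("patient_id", "technique", "structure", "dvh")],
                plans = x$plans))
  }
  manifest <- if (is.character(x) && length(x) == 1L) read_manifest(x) else tibble::as_tibble(x)
  need <- c("patient_id", "technique", "structure", "path")
  if (!all(need %in% names(manifest))) {
    abort_validation("Manifest table needs columns %s.", paste(need, collapse = ", "))
  }
  missing <- manifest[!file.exists(manifest$path), ]
  if (nrow(missing)) {
    abort_validation("DVH file missing for patient %s, structure %s (%s): %s",
                     missing$patient_id[1], missing$structure[1],
                     missing$technique[1], missing$path[1])
  }
  dvhs <- manifest |>
    dplyr::mutate(dvh = purrr::map(.data$path, read_dvh)) |>
    dplyr::select("patient_id", "technique", "structure", "dvh")
  plans <- if ("monitor_units" %in% names(manifest)) {
    dplyr::distinct(manifest, .data$patient_id, .data$technique,
                    .data$monitor_units)
  } else {
    dplyr::distinct(manifest, .data$patient_id, .data$technique) |>
      dplyr::mutate(monitor_units = NA_real_)
  }
  list(dvhs = dvhs, plans = plans)
}

#' Per-plan metric records
#'
#' Evaluates the metric sheet against every DVH in a plan set and returns
#' tidy records, one row per (patient, technique, structure, metric) -
#' the long format consumed by [cohort_summary()] and
#' [compare_techniques()]. Monitor units, when present, are appended as
#' `structure = "Plan", metric = "MU"` rows.
#'
#' @param x A `dvh_cohort`, a manifest path, or a manifest tibble.
#' @param metric_sheet Structure-to-metric mapping
#'   (default [default_metric_sheet()]).
#' @return A tibble with `patient_id`, `technique`, `structure`, `metric`,
#'   `value`, `unit`.
#' @export
plan_records <- function(x, metric_sheet = default_metric_sheet()) {
  set <- load_plan_set(x)
  metric_sheet <- tibble::as_tibble(metric_sheet)
  recs <- purrr::pmap(set$dvhs, function(patient_id, technique, structure, dvh) {
    labels <- metric_sheet$metric[metric_sheet$structure == structure]
    if (!length(labels)) labels <- c("Dmean", "Dmax")
    out <- dvh_metrics(as_cumulative(dvh), labels)
    tibble::tibble(patient_id = patient_id, technique = technique,
                   structure = structure, metric = out$metric,
                   value = out$value, unit = out$unit)
  }) |> dplyr::bind_rows()
  mu <- set$plans |>
    dplyr::filter(!is.na(.data$monitor_units)) |>
    dplyr::transmute(.data$patient_id, .data$technique, structure = "Plan",
                     metric = "MU", value = .data$monitor_units, unit = "MU")
  dplyr::bind_rows(recs, mu)
}

#' Per-plan criteria evaluation
#'
#' Applies a criteria sheet to every plan: each criterion row is matched
#' to its structure's DVH and reported with the measured value. A
#' structure named by the sheet but absent from a plan is an error naming
#' the patient and structure.
#'
#' @inheritParams plan_records
#' @param criteria Criteria sheet with columns `structure`, `metric`,
#'   `comparator`, `threshold` (default [default_criteria()]).
#' @return A tibble with one row per plan and criterion, including `pass`.
#' @export
plan_criteria <- function(x, criteria = default_criteria()) {
  set <- load_plan_set(x)
  criteria <- tibble::as_tibble(criteria)
  plans <- dplyr::distinct(set$dvhs, .data$patient_id, .data$technique)
  purrr::pmap(plans, function(patient_id, technique) {
    here <- set$dvhs[set$dvhs$patient_id == patient_id &
                       set$dvhs$technique == technique, ]
    missing <- setdiff(unique(criteria$structure), here$structure)
    if (length(missing)) {
      abort_validation("Patient %s (%s) lacks structure(s) named by the criteria sheet: %s.",
                       patient_id, technique, paste(missing, collapse = ", "))
    }
    purrr::map(unique(criteria$structure), function(s) {
      res <- evaluate_criteria(as_cumulative(here$dvh[[which(here$structure == s)[1]]]),
                               criteria[criteria$structure == s, ])
      dplyr::bind_cols(tibble::tibble(patient_id = patient_id,
                                      technique = technique), res)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Per-plan TCP and NTCP
#'
#' Computes the tumour control probability from the target structure's
#' DVH (tumorlet product, [tcp()]) and the rectal complication probability
#' from the OAR DVH ([ntcp()]), reporting the effective volume, reference
#' dose and probit argument alongside for auditability. The target
#' structure must be named explicitly - coverage models are meaningful for
#' the PTV or the CTV, and the two differ.
#'
#' @inheritParams plan_records
#' @param target Structure used for TCP (default `"PTV"`).
#' @param oar Structure used for NTCP (default `"Rectum"`).
#' @param params A list with `tcp` and `ntcp` parameter objects, as from
#'   [read_model_params()].
#' @return A tibble with one row per plan: `tcp`, `ntcp`, `veff`, `d_ref`,
#'   `t`.
#' @export
plan_radiobiology <- function(x, target = "PTV", oar = "Rectum",
                              params = read_model_params()) {
  set <- load_plan_set(x)
  plans <- dplyr::distinct(set$dvhs, .data$patient_id, .data$technique)
  purrr::pmap(plans, function(patient_id, technique) {
    here <- set$dvhs[set$dvhs$patient_id == patient_id &
                       set$dvhs$technique == technique, ]
    for (s in c(target, oar)) {
      if (!s %in% here$structure) {
        abort_validation("Patient %s (%s) lacks structure %s.", patient_id, technique, s)
      }
    }
    tv <- tcp(here$dvh[[which(here$structure == target)]], params$tcp)
    nv <- ntcp(here$dvh[[which(here$structure == oar)]], params$ntcp)
    tibble::tibble(patient_id = patient_id, technique = technique,
                   tcp = tv, ntcp = nv$ntcp, veff = nv$veff,
                   d_ref = nv$d_ref, t = nv$t)
  }) |> dplyr::bind_rows()
}

write_table_output <- function(tbl, out, format, seed = NULL) {
  if (is.null(out)) return(invisible(tbl))
  if (format == "json") {
    jsonlite::write_json(list(seed = seed, results = tbl), out,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows", pretty = TRUE)
  } else {
    con <- file(out, "w")
    on.exit(close(con))
    if (!is.null(seed)) writeLines(sprintf("# seed=%d", seed), con)
    utils::write.csv(tbl, con, row.names = FALSE)
  }
  invisible(tbl)
}

#' Pipeline commands
#'
#' The four end-to-end drivers behind the `planrad` command-line script;
#' each is an ordinary R function so the pipeline is equally usable from
#' scripts and interactive sessions. All are deterministic given their
#' inputs (and, for `cmd_simulate()`, the seed).
#'
#' * `cmd_metrics()`: metric records plus criteria evaluation per plan.
#' * `cmd_radiobio()`: TCP/NTCP table with `veff` and `t` intermediates.
#' * `cmd_compare()`: cohort comparison report across techniques,
#'   including MU and (optionally) TCP/NTCP rows.
#' * `cmd_simulate()`: write a synthetic cohort and return its manifest.
#'
#' @param manifest A manifest path, manifest tibble, or `dvh_cohort`.
#' @param criteria Criteria sheet (default [default_criteria()]).
#' @param params Model parameters ([read_model_params()] result or a path
#'   to a JSON/YAML parameter file).
#' @param radiobiology Include TCP/NTCP rows in the comparison report.
#' @param reference Reference technique label for comparisons.
#' @param out Optional output file.
#' @param format Output format for `out`.
#' @param seed Seed recorded in outputs / driving the simulation.
#' @param n_patients,dir Simulation size and output directory.
#' @return `cmd_metrics()`: list of `records` and `criteria` tibbles.
#'   `cmd_radiobio()`: a tibble. `cmd_compare()`: a `cohort_report`.
#'   `cmd_simulate()`: the manifest path.
#' @export
cmd_metrics <- function(manifest, criteria = default_criteria(), out = NULL,
                        format = c("csv", "json"), seed = NULL) {
  format <- match.arg(format)
  records <- plan_records(manifest)
  crit <- plan_criteria(manifest, criteria)
  if (!is.null(out)) {
    write_table_output(records, out, format, seed)
    write_table_output(crit, sub("(\\.[a-z]+)?$", "_criteria\\1", out), format, seed)
  }
  list(records = records, criteria = crit)
}

#' @rdname cmd_metrics
#' @export
cmd_radiobio <- function(manifest, params = NULL, target = "PTV",
                         oar = "Rectum", out = NULL,
                         format = c("csv", "json"), seed = NULL) {
  format <- match.arg(format)
  if (is.null(params) || is.character(params)) {
    params <- read_model_params(params)
  }
  tbl <- plan_radiobiology(manifest, target = target, oar = oar, params = params)
  write_table_output(tbl, out, format, seed)
  tbl
}

#' @rdname cmd_metrics
#' @export
cmd_compare <- function(manifest, reference = "single-arc",
                        radiobiology = TRUE, params = NULL,
                        out = NULL, format = c("text", "csv", "json"),
                        seed = NULL) {
  format <- match.arg(format)
  set <- load_plan_set(manifest)
  records <- plan_records(set)
  if (radiobiology && all(c("PTV", "Rectum") %in% set$dvhs$structure)) {
    if (is.null(params) || is.character(params)) params <- read_model_params(params)
    rb <- plan_radiobiology(set, params = params)
    records <- dplyr::bind_rows(
      records,
      dplyr::transmute(rb, .data$patient_id, .data$technique,
                       structure = "PTV", metric = "TCP", value = .data$tcp,
                       unit = "probability"),
      dplyr::transmute(rb, .data$patient_id, .data$technique,
                       structure = "Rectum", metric = "NTCP",
                       value = .data$ntcp, unit = "probability"))
  }
  report <- compare_techniques(records, reference = reference)
  if (!is.null(out)) render_report(report, format, out)
  report
}

#' @rdname cmd_metrics
#' @export
cmd_simulate <- function(dir, n_patients = 5, seed = 1, ...) {
  cohort <- generate_cohort(cohort_config(n_patients = n_patients,
                                          seed = seed, ...), dir = dir)
  cohort$manifest
}
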