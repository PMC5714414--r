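#' Generate a synthetic target-structure cumulative DVH
#'
#' Target (PTV-like) DVHs from a sharply conformal arc plan are nearly
#' ideal step functions softened by dose heterogeneity: the cumulative
#' curve is modelled as a probit fall-off `V(D) = Phi((Dc - D) / sigma)`.
#' `(Dc, sigma)` are solved in closed form so that the realised curve hits
#' the requested coverage and maximum dose exactly: `V(d99) = 0.99` and
#' `V(dmax) = 1e-3` (the DVH is truncated at `dmax`, so the measured
#' [max_dose()] equals `dmax`). Both targets are therefore recovered by
#' [dose_at_volume()] up to linear-interpolation error on the dose grid,
#' well under half a bin.
#'
#' @param d99 Requested D99% in Gy.
#' @param dmax Requested maximum dose in Gy; must exceed `d99`.
#' @param bin_width Dose grid spacing in Gy (default 0.1).
#' @param structure,total_volume,patient_id,technique Metadata passed to
#'   [cumulative_dvh()].
#' @return A `cumulative_dvh`.
#' @examples
#' ptv <- generate_target_dvh(d99 = 74.6, dmax = 82.8)
#' dose_at_volume(ptv, 99)
#' @export
generate_target_dvh <- function(d99, dmax, bin_width = 0.1,
                                structure = "PTV", total_volume = NA_real_,
                                patient_id = NA_character_,
                                technique = NA_character_) {
  stopifnot_scalar_number(d99, "d99")
  stopifnot_scalar_number(dmax, "dmax")
  if (d99 <= 0) abort_infeasible("`d99` must be positive.")
  if (dmax <= d99) {
    abort_infeasible("Infeasible target DVH: dmax (%g) must exceed d99 (%g).", dmax, d99)
  }
  z99 <- stats::qnorm(0.99)
  z_tail <- -stats::qnorm(1e-3)
  sigma <- (dmax - d99) / (z99 + z_tail)
  dc <- d99 + z99 * sigma
  grid <- dose_grid(dmax, bin_width)
  v <- stats::pnorm((dc - grid) / sigma)
  v[1] <- 1
  cumulative_dvh(grid, v, structure = structure, total_volume = total_volume,
                 patient_id = patient_id, technique = technique)
}

#' Generate a synthetic organ-at-risk cumulative DVH
#'
#' Two OAR archetypes from prostate arc plans are emulated:
#'
#' * `role = "overlap_oar"` (rectum, bladder): a fraction `f` of the organ
#'   overlaps the high-dose target region and receives near-prescription
#'   dose (probit component centred at `overlap_dose`), while the rest sees
#'   a monotone low/intermediate-dose bath modelled as a stretched
#'   exponential `(1 - f) * exp(-(D / tau)^k)`. Given the requested
#'   `v17`/`v35` (percent volume at 17 and 35 Gy), `(f, tau)` are solved
#'   exactly - `f` by root finding, `tau` in closed form - so the measured
#'   [volume_at_dose()] reproduces both targets; `k` is the `tail_shape`.
#' * `role = "lateral_oar"` (femoral heads): no target overlap; a pure
#'   stretched-exponential fall-off whose `(k, tau)` are solved from the
#'   requested `d5` (D5%) and `dmax` (`V(dmax) = 1e-3`, the truncation
#'   point).
#'
#' A requested pair that no curve of the family can satisfy (e.g.
#' `v35 >= v17`, or a `tail_shape` too shallow for the `v17`/`v35`
#' combination) raises an infeasibility error rather than a distorted DVH.
#'
#' @param role `"overlap_oar"` or `"lateral_oar"`.
#' @param v17,v35 Percent volume receiving at least 17 / 35 Gy
#'   (overlap role).
#' @param overlap_dose Centre (Gy) of the near-prescription overlap
#'   component (overlap role).
#' @param tail_shape Stretched-exponential shape `k` of the low-dose tail
#'   (overlap role; default 1.6).
#' @param adapt_tail Some `v17`/`v35` pairs require a steeper tail than the
#'   requested `tail_shape` to coexist with a positive overlap fraction;
#'   with `adapt_tail = TRUE` (default) the shape is raised to the smallest
#'   feasible value for such draws, with `FALSE` they are an error.
#' @param overlap_sigma Width (Gy) of the overlap fall-off (default 1).
#' @param d5,dmax D5% and maximum dose in Gy (lateral role).
#' @inheritParams generate_target_dvh
#' @return A `cumulative_dvh`.
#' @examples
#' rectum <- generate_oar_dvh("overlap_oar", v17 = 61.1, v35 = 29.6,
#'                            overlap_dose = 79.8, structure = "Rectum")
#' volume_at_dose(rectum, c(17, 35))
#' @export
generate_oar_dvh <- function(role = c("overlap_oar", "lateral_oar"),
                             v17 = NULL, v35 = NULL, overlap_dose = NULL,
                             tail_shape = 1.6, adapt_tail = TRUE,
                             overlap_sigma = 1,
                             d5 = NULL, dmax = NULL,
                             bin_width = 0.1, structure = "OAR",
                             total_volume = NA_real_,
                             patient_id = NA_character_,
                             technique = NA_character_) {
  role <- match.arg(role)
  if (role == "overlap_oar") {
    for (nm in c("v17", "v35", "overlap_dose")) {
      if (is.null(get(nm))) abort_validation("overlap_oar needs `%s`.", nm)
    }
    shape <- solve_overlap_shape(v17 / 100, v35 / 100, tail_shape, adapt_tail)
    if (overlap_dose <= 50) {
      abort_infeasible("`overlap_dose` (%g Gy) must sit well above 35 Gy.", overlap_dose)
    }
    top <- overlap_dose + 3.5 * overlap_sigma
    grid <- dose_grid(top, bin_width)
    v <- shape$f * stats::pnorm((overlap_dose - grid) / overlap_sigma) +
      (1 - shape$f) * exp(-(grid / shape$tau)^shape$k)
    v[1] <- 1
  } else {
    for (nm in c("d5", "dmax")) {
      if (is.null(get(nm))) abort_validation("lateral_oar needs `%s`.", nm)
    }
    if (d5 <= 0 || dmax <= d5) {
      abort_infeasible("lateral_oar needs 0 < d5 < dmax (got d5 = %g, dmax = %g).", d5, dmax)
    }
    k <- log(log(1e-3) / log(0.05)) / log(dmax / d5)
    tau <- d5 / (-log(0.05))^(1 / k)
    grid <- dose_grid(dmax, bin_width)
    v <- exp(-(grid / tau)^k)
    v[1] <- 1
  }
  cumulative_dvh(grid, v, structure = structure, total_volume = total_volume,
                 patient_id = patient_id, technique = technique)
}

# Solve the overlap fraction f and tail scale tau so that
# V(17) = a and V(35) = b for V(D) = f + (1-f) exp(-(D/tau)^k)
# (the overlap probit is saturated at 1 for D <= 35 Gy).
solve_overlap_shape <- function(a, b, k, adapt = TRUE) {
  if (!(a > 0 && b > 0 && b < a && a < 1)) {
    abort_infeasible("Need 0 < V35Gy < V17Gy < 100 (got %g, %g percent).",
                     100 * a, 100 * b)
  }
  ratio <- function(f) {
    log((b - f) / (1 - f)) / log((a - f) / (1 - f))
  }
  # with f = 0 the tail alone must carry both targets; that fixes the
  # smallest shape k able to pair them with a nonnegative overlap fraction
  k_min <- log(ratio(0)) / log(35 / 17)
  if (k < k_min) {
    if (!adapt) {
      abort_infeasible(
        "tail_shape %g is too shallow for V17Gy = %g%%, V35Gy = %g%%; increase it.",
        k, 100 * a, 100 * b)
    }
    k <- k_min + 0.05
  }
  r_target <- (35 / 17)^k
  f <- if (abs(ratio(0) - r_target) < 1e-12) 0 else {
    stats::uniroot(function(f) ratio(f) - r_target,
                   lower = 0, upper = b - 1e-9, tol = 1e-12)$root
  }
  tau <- 17 / (-log((a - f) / (1 - f)))^(1 / k)
  list(f = f, tau = tau, k = k)
}

dose_grid <- function(top, bin_width) {
  if (!is_scalar_number(bin_width) || bin_width <= 0) {
    abort_validation("`bin_width` must be positive.")
  }
  n <- ceiling(top / bin_width - 1e-9)
  grid <- seq(0, by = bin_width, length.out = n + 1L)
  grid[length(grid)] <- top  # land exactly on the truncation dose
  grid
}

#' Synthetic cohort configuration
#'
#' Describes the cohort the generator emulates: a set of patients each
#' planned with two arc techniques on the same anatomy. The default
#' structure models encode the bundled reference summary
#' ([prostate_vmat_summary()]) as generation targets: per structure and
#' technique, the target-metric means and SDs that between-patient draws
#' should realise, the organ-volume range, and the shape parameters of the
#' DVH family.
#'
#' @param n_patients Number of patients (>= 1; default 5).
#' @param seed Integer seed; the cohort is a pure function of
#'   (config, seed).
#' @param prescription_dose Prescription in Gy (default 78, delivered in
#'   39 fractions; all doses are total physical course doses).
#' @param bin_width DVH grid spacing in Gy.
#' @param models Structure-model table, see [default_structure_models()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 5, seed = 1, prescription_dose = 78,
                          bin_width = 0.1, models = default_structure_models()) {
  if (!is_scalar_number(n_patients) || n_patients < 1) {
    abort_validation("`n_patients` must be >= 1.")
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         prescription_dose = prescription_dose, bin_width = bin_width,
         models = tibble::as_tibble(models)),
    class = "cohort_config")
}

#' Default structure models for the synthetic prostate cohort
#'
#' One row per structure and technique. Columns `*_mean` / `*_sd` are the
#' generation targets (Gy for D-metrics, percent for V-metrics), sampled
#' per patient; `volume_lo`/`volume_hi` bound the absolute structure
#' volume in cm^3. For the rectum the double-arc overlap component is
#' centred slightly higher than the single-arc one, reflecting the hotter
#' target-overlap region that drives its complication probability.
#'
#' @return A tibble consumed by [generate_cohort()].
#' @export
default_structure_models <- function() {
  tibble::tribble(
    ~structure, ~role, ~technique, ~volume_lo, ~volume_hi,
    ~d99_mean, ~d99_sd, ~dmax_mean, ~dmax_sd,
    ~v17_mean, ~v17_sd, ~v35_mean, ~v35_sd,
    ~d5_mean, ~d5_sd, ~overlap_dose_mean, ~overlap_dose_sd, ~tail_shape,

    "PTV", "target", "single-arc", 107, 196.1,
    72.5, 0.8, 82.7, 0.8, NA, NA, NA, NA, NA, NA, NA, NA, NA,
    "PTV", "target", "double-arc", 107, 196.1,
    74.6, 0.4, 82.8, 0.7, NA, NA, NA, NA, NA, NA, NA, NA, NA,

    "Rectum", "overlap_oar", "single-arc", 42.3, 110.1,
    NA, NA, NA, NA, 61.1, 8.5, 29.6, 5.9, NA, NA, 79.8, 0.5, 1.6,
    "Rectum", "overlap_oar", "double-arc", 42.3, 110.1,
    NA, NA, NA, NA, 47.7, 9.0, 25.1, 4.9, NA, NA, 80.4, 0.5, 1.6,

    "Bladder", "overlap_oar", "single-arc", 182.5, 552.6,
    NA, NA, NA, NA, 40.7, 9.8, 25.1, 5.3, NA, NA, 80.2, 1.0, 1.6,
    "Bladder", "overlap_oar", "double-arc", 182.5, 552.6,
    NA, NA, NA, NA, 35.4, 7.8, 20.8, 4.9, NA, NA, 80.2, 1.0, 1.6,

    "LeftFemoralHead", "lateral_oar", "single-arc", 146.6, 201.4,
    NA, NA, 40.4, 5.7, NA, NA, NA, NA, 31.0, 6.6, NA, NA, NA,
    "LeftFemoralHead", "lateral_oar", "double-arc", 146.6, 201.4,
    NA, NA, 49.4, 2.4, NA, NA, NA, NA, 41.6, 2.1, NA, NA, NA,

    "RightFemoralHead", "lateral_oar", "single-arc", 153.4, 246.0,
    NA, NA, 38.9, 3.8, NA, NA, NA, NA, 28.4, 4.9, NA, NA, NA,
    "RightFemoralHead", "lateral_oar", "double-arc", 153.4, 246.0,
    NA, NA, 47.1, 5.8, NA, NA, NA, NA, 39.4, 3.9, NA, NA, NA
  )
}

#' Generate a synthetic patient cohort
#'
#' Draws `n_patients` anatomies and, for each, one plan per technique.
#' Between-patient variation uses one latent standard-normal effect per
#' (patient, structure), built from jittered stratified quantiles - the
#' patient effects tile the quantile range, so the realised cohort mean of
#' every target metric sits close to its configured mean even at n = 5 -
#' and the effect is *shared* between the two techniques of a patient,
#' mirroring paired planning on the same anatomy. Structure volumes are
#' likewise drawn once per patient. The whole cohort is reproducible from
#' the seed, patient by patient.
#'
#' Per-patient monitor units are fixture constants from the reference
#' cohort (attached only for the default five-patient size); MU is a
#' delivery property that the DVH generator makes no attempt to model.
#'
#' @param config A [cohort_config()].
#' @param dir Optional directory: when given, every DVH is written as a
#'   CSV file under `dir/<patient>/<technique>/` together with a
#'   `manifest.json`, and the manifest path is returned in the result.
#' @return A `dvh_cohort`: list with `dvhs` (tibble of `patient_id`,
#'   `technique`, `structure`, `role`, `dvh` list-column), `plans`
#'   (per-plan monitor units), `config`, and `manifest` (path or `NA`).
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 2, seed = 7))
#' coh$dvhs
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  models <- config$models
  pids <- sprintf("pt%02d", seq_len(n))
  set.seed(config$seed)
  structures <- unique(models[, c("structure", "role", "volume_lo", "volume_hi")])
  latent <- purrr::pmap(structures, function(structure, role, volume_lo, volume_hi) {
    perm <- sample.int(n)
    z <- stats::qnorm((perm - 1 + stats::runif(n)) / n)
    vol <- stats::runif(n, volume_lo, volume_hi)
    tibble::tibble(structure = structure, patient_id = pids, z = z, volume = vol)
  }) |> dplyr::bind_rows()

  rows <- models |>
    dplyr::left_join(latent, by = "structure", relationship = "many-to-many")
  dvhs <- purrr::pmap(rows, function(structure, role, technique, patient_id,
                                     z, volume, ...) {
    m <- list(...)
    dvh <- switch(role,
      target = {
        d99 <- m$d99_mean + m$d99_sd * z
        dmax <- m$dmax_mean + m$dmax_sd * z
        if (dmax < d99 + 0.5) dmax <- d99 + 0.5
        generate_target_dvh(d99, dmax, bin_width = config$bin_width,
                            structure = structure, total_volume = volume,
                            patient_id = patient_id, technique = technique)
      },
      overlap_oar = {
        v17 <- min(max(m$v17_mean + m$v17_sd * z, 1), 99)
        v35 <- min(max(m$v35_mean + m$v35_sd * z, 0.5), v17 - 1)
        generate_oar_dvh("overlap_oar", v17 = v17, v35 = v35,
                         overlap_dose = m$overlap_dose_mean + m$overlap_dose_sd * z,
                         tail_shape = m$tail_shape,
                         bin_width = config$bin_width,
                         structure = structure, total_volume = volume,
                         patient_id = patient_id, technique = technique)
      },
      lateral_oar = {
        d5 <- max(m$d5_mean + m$d5_sd * z, 1)
        dmax <- m$dmax_mean + m$dmax_sd * z
        if (dmax < d5 + 2) dmax <- d5 + 2
        generate_oar_dvh("lateral_oar", d5 = d5, dmax = dmax,
                         bin_width = config$bin_width,
                         structure = structure, total_volume = volume,
                         patient_id = patient_id, technique = technique)
      },
      abort_validation("Unknown structure role '%s'.", role)
    )
    tibble::tibble(patient_id = patient_id, technique = technique,
                   structure = structure, role = role, dvh = list(dvh))
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$patient_id, .data$technique, .data$structure)

  plans <- tidyr::expand_grid(patient_id = pids,
                              technique = unique(models$technique))
  mu <- prostate_vmat_mu()
  plans <- dplyr::left_join(plans, mu, by = c("patient_id", "technique"))
  if (n != 5) plans$monitor_units <- NA_real_

  cohort <- structure(
    list(dvhs = dvhs, plans = plans, config = config, manifest = NA_character_),
    class = "dvh_cohort")
  if (!is.null(dir)) cohort$manifest <- write_cohort(cohort, dir)
  cohort
}

#' @export
print.dvh_cohort <- function(x, ...) {
  cat(sprintf("<dvh_cohort> %d patients x %d techniques, %d DVHs (seed %d)\n",
              length(unique(x$dvhs$patient_id)),
              length(unique(x$dvhs$technique)),
              nrow(x$dvhs), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' One DVH CSV per structure under `dir/<patient>/<technique>/`, plus a
#' `manifest.json` mapping the cohort for the manifest-driven commands.
#' Output is byte-deterministic for a fixed config and seed.
#'
#' @param cohort A `dvh_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dvh_cohort"))
  entries <- cohort$dvhs |>
    dplyr::mutate(path = file.path(.data$patient_id, .data$technique,
                                   paste0(.data$structure, ".csv")))
  for (i in seq_len(nrow(entries))) {
    full <- file.path(dir, entries$path[i])
    dir.create(dirname(full), recursive = TRUE, showWarnings = FALSE)
    write_dvh(entries$dvh[[i]], full)
  }
  entries <- entries |>
    dplyr::left_join(cohort$plans, by = c("patient_id", "technique")) |>
    dplyr::select("patient_id", "technique", "structure", "path", "monitor_units")
  manifest <- file.path(dir, "manifest.json")
  write_manifest(entries, manifest)
  cfg <- cohort$config
  jsonlite::write_json(
    list(seed = cfg$seed, n_patients = cfg$n_patients,
         prescription_dose = cfg$prescription_dose, bin_width = cfg$bin_width),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
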