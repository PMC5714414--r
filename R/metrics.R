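#' Dose-volume metrics
#'
#' Clinical point metrics extracted from a cumulative DVH with linear
#' interpolation between samples (no smoothing, so monotone curves give
#' monotone metrics and every value is reproducible by hand).
#'
#' `dose_at_volume()` returns Dx%: the minimum dose received by the hottest
#' `x`% of the structure, i.e. the dose where the cumulative curve crosses
#' the volume fraction `x/100` coming down. On a segment where the curve sits
#' exactly at the target fraction, the lower dose of the flat run is
#' returned; the one exception is a leading plateau at the target (the
#' `x = 100` case), where the plateau's end - the structure's minimum dose -
#' is the clinically meaningful value. If the curve never falls below the
#' target, the last sampled dose is returned.
#'
#' `volume_at_dose()` returns VxGy as a percentage: `100 * V(d)` by linear
#' interpolation, 100 at zero dose and 0 beyond the last sample.
#'
#' `mean_dose()` is the volume-weighted mean `sum(v_i * D_i)` of the
#' differential form (a cumulative DVH is converted first), and
#' `max_dose()` is the largest dose at which the cumulative volume still
#' exceeds `epsilon_volume` (a DVH-resolution maximum, not a 3D point dose).
#'
#' @param x A DVH object (`dose_at_volume`, `volume_at_dose` and `max_dose`
#'   require the cumulative form).
#' @param volume_pct Volume level(s) in percent, in (0, 100].
#' @param dose Dose level(s) in Gy, >= 0.
#' @param epsilon_volume Volume fraction defining a near-maximum dose
#'   (default 0: the dose where the DVH reaches zero volume).
#' @return Dose in Gy (`dose_at_volume`, `mean_dose`, `max_dose`) or volume
#'   in percent (`volume_at_dose`), vectorised over the level argument.
#' @examples
#' c1 <- cumulative_dvh(c(0, 40, 60, 78, 80), c(1, 1, 0.8, 0.3, 0))
#' dose_at_volume(c1, 50)   # 70.8 Gy
#' volume_at_dose(c1, 69)   # 55 %
#' max_dose(c1)             # 80 Gy
#' @export
dose_at_volume <- function(x, volume_pct) {
  stopifnot(inherits(x, "cumulative_dvh"))
  vapply(volume_pct, dose_at_volume_1, numeric(1), x = x)
}

dose_at_volume_1 <- function(x, volume_pct) {
  if (!is_scalar_number(volume_pct) || volume_pct <= 0 || volume_pct > 100) {
    abort_validation("Volume level must be in (0, 100] percent (got %g).", volume_pct)
  }
  target <- volume_pct / 100
  d <- x$dose
  v <- x$volume
  exact <- which(abs(v - target) <= 1e-12)
  if (length(exact)) {
    run_end <- exact[1]
    while (run_end + 1L <= length(v) && abs(v[run_end + 1L] - target) <= 1e-12) {
      run_end <- run_end + 1L
    }
    # leading plateau at the target: its end is the dose where coverage is lost
    if (exact[1] == 1L) return(d[run_end])
    return(d[exact[1]])
  }
  j <- which(v < target)[1]
  if (is.na(j)) return(d[length(d)])
  if (j == 1L) return(d[1L])
  d[j - 1L] + (v[j - 1L] - target) / (v[j - 1L] - v[j]) * (d[j] - d[j - 1L])
}

#' @rdname dose_at_volume
#' @export
volume_at_dose <- function(x, dose) {
  stopifnot(inherits(x, "cumulative_dvh"))
  vapply(dose, function(dd) {
    if (!is_scalar_number(dd) || dd < 0) {
      abort_validation("Dose level must be non-negative (got %g).", dd)
    }
    if (dd > max(x$dose)) return(0)
    100 * stats::approx(x$dose, x$volume, xout = dd, rule = 2)$y
  }, numeric(1))
}

#' @rdname dose_at_volume
#' @export
mean_dose <- function(x) {
  stopifnot(inherits(x, "dvh"))
  d <- as_differential(x)
  sum(d$volume * d$dose)
}

#' @rdname dose_at_volume
#' @export
max_dose <- function(x, epsilon_volume = 0) {
  stopifnot(inherits(x, "cumulative_dvh"))
  if (!is_scalar_number(epsilon_volume) || epsilon_volume < 0 || epsilon_volume >= 1) {
    abort_validation("`epsilon_volume` must be a fraction in [0, 1).")
  }
  d <- x$dose
  v <- x$volume
  above <- which(v > epsilon_volume)
  if (!length(above)) return(0)
  j <- above[length(above)]
  if (j == length(v)) return(d[j])
  d[j] + (v[j] - epsilon_volume) / (v[j] - v[j + 1L]) * (d[j + 1L] - d[j])
}

#' Metric specifications and batch extraction
#'
#' Metrics are named by their clinical labels: `"D30%"` (dose to the
#' hottest 30% of the volume), `"V17Gy"` (percent volume receiving at
#' least 17 Gy), `"Dmean"`, `"Dmax"`. `parse_metric()` turns a label into
#' its kind and parameter; `dvh_metrics()` evaluates a vector of labels
#' against one DVH and returns a tidy table.
#'
#' @param label Metric label string(s).
#' @return `parse_metric()`: a tibble with `label`, `kind`, `parameter`.
#'   `dvh_metrics()`: a tibble with `structure`, `metric`, `value`, `unit`.
#' @examples
#' c1 <- cumulative_dvh(c(0, 40, 60, 78, 80), c(1, 1, 0.8, 0.3, 0))
#' dvh_metrics(c1, c("D50%", "V35Gy", "Dmean", "Dmax"))
#' @export
parse_metric <- function(label) {
  rows <- lapply(label, function(lb) {
    if (grepl("^D[0-9.]+%$", lb)) {
      p <- as.numeric(sub("^D([0-9.]+)%$", "\\1", lb))
      if (p <= 0 || p > 100) abort_validation("Volume percent out of (0,100] in '%s'.", lb)
      tibble::tibble(label = lb, kind = "D_at_volume", parameter = p)
    } else if (grepl("^V[0-9.]+Gy$", lb)) {
      p <- as.numeric(sub("^V([0-9.]+)Gy$", "\\1", lb))
      tibble::tibble(label = lb, kind = "V_at_dose", parameter = p)
    } else if (lb %in% c("Dmean", "mean")) {
      tibble::tibble(label = lb, kind = "mean", parameter = NA_real_)
    } else if (lb %in% c("Dmax", "max")) {
      tibble::tibble(label = lb, kind = "max", parameter = NA_real_)
    } else {
      abort_validation("Unknown metric label '%s' (expected Dx%%, VxGy, Dmean or Dmax).", lb)
    }
  })
  dplyr::bind_rows(rows)
}

#' @rdname parse_metric
#' @param x A `cumulative_dvh`.
#' @export
dvh_metrics <- function(x, label) {
  spec <- parse_metric(label)
  value <- purrr::map2_dbl(spec$kind, spec$parameter, function(kind, p) {
    switch(kind,
      D_at_volume = dose_at_volume(x, p),
      V_at_dose = volume_at_dose(x, p),
      mean = mean_dose(x),
      max = max_dose(x)
    )
  })
  tibble::tibble(
    structure = attr(x, "structure"),
    metric = spec$label,
    value = value,
    unit = ifelse(spec$kind == "V_at_dose", "%", "Gy")
  )
}

#' Evaluate plan dose-volume criteria
#'
#' Applies a criteria sheet - rows of (metric label, comparator,
#' threshold) - to one structure's cumulative DVH and reports the measured
#' value alongside each pass/fail. Matching criteria rows to the right
#' structure is the caller's responsibility (see [plan_metrics()] for the
#' manifest-level driver); nothing is skipped silently.
#'
#' @param x A `cumulative_dvh`.
#' @param criteria A data frame with columns `metric`, `comparator`
#'   (`"<="` or `">="`), `threshold`; a `structure` column, if present, is
#'   carried through untouched.
#' @return A tibble with `metric`, `measured`, `comparator`, `threshold`,
#'   `pass`.
#' @examples
#' ptv <- cumulative_dvh(c(0, 70, 74.6, 83), c(1, 1, 0.99, 0))
#' evaluate_criteria(ptv, default_criteria()[1, ])
#' @export
evaluate_criteria <- function(x, criteria) {
  criteria <- tibble::as_tibble(criteria)
  if (!nrow(criteria)) {
    return(tibble::tibble(metric = character(), measured = numeric(),
                          comparator = character(), threshold = numeric(),
                          pass = logical()))
  }
  if (!all(c("metric", "comparator", "threshold") %in% names(criteria))) {
    abort_validation("Criteria need columns metric, comparator, threshold.")
  }
  if (!all(criteria$comparator %in% c("<=", ">="))) {
    abort_validation("Criterion comparator must be '<=' or '>='.")
  }
  if (!all(is.finite(criteria$threshold))) {
    abort_validation("Criterion thresholds must be finite.")
  }
  measured <- dvh_metrics(x, criteria$metric)$value
  pass <- ifelse(criteria$comparator == "<=",
                 measured <= criteria$threshold,
                 measured >= criteria$threshold)
  out <- tibble::tibble(metric = criteria$metric, measured = measured,
                        comparator = criteria$comparator,
                        threshold = criteria$threshold, pass = pass)
  if ("structure" %in% names(criteria)) {
    out <- dplyr::bind_cols(tibble::tibble(structure = criteria$structure), out)
  }
  out
}

#' Default prostate-plan evaluation criteria
#'
#' The standard evaluation sheet for a 78 Gy prostate arc plan: PTV
#' coverage D99% at or above 95% of prescription (74.1 Gy), rectum and
#' bladder D30% <= 70 Gy and D50% <= 53 Gy, femoral-head D5% <= 53 Gy.
#'
#' @return A tibble with columns `structure`, `metric`, `comparator`,
#'   `threshold`.
#' @export
default_criteria <- function() {
  tibble::tribble(
    ~structure,         ~metric, ~comparator, ~threshold,
    "PTV",              "D99%",  ">=",        74.1,
    "Rectum",           "D30%",  "<=",        70,
    "Rectum",           "D50%",  "<=",        53,
    "Bladder",          "D30%",  "<=",        70,
    "Bladder",          "D50%",  "<=",        53,
    "LeftFemoralHead",  "D5%",   "<=",        53,
    "RightFemoralHead", "D5%",   "<=",        53
  )
}
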