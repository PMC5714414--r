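#' Dose-volume histogram objects
#'
#' A DVH summarises a 3D dose distribution for one contoured structure.
#' `cumulative_dvh()` builds the cumulative form: `volume` is the fraction of
#' the structure receiving at least `dose` Gy, sampled at increasing dose
#' values that start at 0 Gy. `differential_dvh()` builds the differential
#' form: `volume` is the fraction of the structure falling in the dose bin
#' centred at `dose`, and the fractions sum to one.
#'
#' Both objects are tibbles with columns `dose` (Gy) and `volume`
#' (dimensionless fraction), carrying the structure metadata as attributes,
#' so they compose directly with dplyr/tidyr verbs. Volumes are kept as
#' relative fractions internally; absolute cm^3 appears only at the file
#' boundary through `total_volume`.
#'
#' Cumulative volume columns may carry numerical noise from planning-system
#' exports: monotonicity violations up to a relative `tol` (default `1e-6`)
#' are clamped, anything larger is rejected with the offending row named.
#'
#' @param dose Numeric vector of doses in Gy. Strictly increasing; the
#'   cumulative form must start at 0 Gy.
#' @param volume Numeric vector of relative volumes (fractions).
#' @param structure Structure label, e.g. `"PTV"` or `"Rectum"`.
#' @param total_volume Absolute structure volume in cm^3 (optional, `NA` if
#'   unknown; required to write files in cm^3).
#' @param patient_id,technique Optional plan labels carried through reports.
#' @param tol Relative tolerance for clamping small monotonicity/range noise.
#' @return A `cumulative_dvh` or `differential_dvh` tibble.
#' @examples
#' c1 <- cumulative_dvh(c(0, 40, 80), c(1, 0.5, 0), structure = "PTV")
#' as_differential(c1)
#' @export
cumulative_dvh <- function(dose, volume, structure = "structure",
                           total_volume = NA_real_,
                           patient_id = NA_character_,
                           technique = NA_character_,
                           tol = 1e-6) {
  validate_dvh_columns(dose, volume)
  if (dose[1] != 0) {
    abort_validation("Cumulative DVH must start at dose 0 Gy (first dose is %g).", dose[1])
  }
  # clamp float noise in [0, 1] range
  hi <- which(volume > 1)
  if (length(hi)) {
    if (any(volume[hi] > 1 + tol)) {
      abort_validation("Cumulative volume exceeds 1 at row %d (value %g).",
                       hi[which.max(volume[hi])], max(volume[hi]))
    }
    volume[hi] <- 1
  }
  lo <- which(volume < 0)
  if (length(lo)) {
    if (any(volume[lo] < -tol)) {
      abort_validation("Negative volume at row %d (value %g).",
                       lo[which.min(volume[lo])], min(volume[lo]))
    }
    volume[lo] <- 0
  }
  if (abs(volume[1] - 1) > tol) {
    abort_validation("Cumulative DVH must have volume fraction 1 at dose 0 (got %g).", volume[1])
  }
  volume[1] <- 1
  up <- which(diff(volume) > 0)
  if (length(up)) {
    bad <- up[diff(volume)[up] > tol]
    if (length(bad)) {
      abort_validation(
        "Cumulative volume increases with dose at row %d (%g -> %g).",
        bad[1] + 1L, volume[bad[1]], volume[bad[1] + 1L])
    }
    volume <- cummin(volume)
  }
  new_dvh(dose, volume, "cumulative_dvh", structure, total_volume, patient_id, technique)
}

#' @rdname cumulative_dvh
#' @export
differential_dvh <- function(dose, volume, structure = "structure",
                             total_volume = NA_real_,
                             patient_id = NA_character_,
                             technique = NA_character_,
                             tol = 1e-9) {
  validate_dvh_columns(dose, volume)
  if (any(volume < 0)) {
    abort_validation("Negative bin volume at row %d.", which(volume < 0)[1])
  }
  s <- sum(volume)
  if (abs(s - 1) > max(tol, 1e-9)) {
    abort_validation("Differential DVH fractions must sum to 1 (sum is %.12g).", s)
  }
  volume <- volume / s
  new_dvh(dose, volume, "differential_dvh", structure, total_volume, patient_id, technique)
}

validate_dvh_columns <- function(dose, volume) {
  if (!is.numeric(dose) || !is.numeric(volume)) {
    abort_validation("`dose` and `volume` must be numeric vectors.")
  }
  if (length(dose) != length(volume)) {
    abort_validation("`dose` and `volume` differ in length (%d vs %d).",
                     length(dose), length(volume))
  }
  if (length(dose) < 1L) abort_validation("DVH needs at least one sample.")
  if (anyNA(dose) || anyNA(volume)) {
    abort_validation("DVH contains missing values (first at row %d).",
                     which(is.na(dose) | is.na(volume))[1])
  }
  d <- diff(dose)
  if (any(d <= 0)) {
    abort_validation("Dose column must be strictly increasing (violated at row %d).",
                     which(d <= 0)[1] + 1L)
  }
  invisible(TRUE)
}

new_dvh <- function(dose, volume, subclass, structure, total_volume,
                    patient_id, technique) {
  out <- tibble::tibble(dose = as.numeric(dose), volume = as.numeric(volume))
  class(out) <- c(subclass, "dvh", class(out))
  attr(out, "structure") <- as.character(structure)
  attr(out, "total_volume") <- as.numeric(total_volume)
  attr(out, "patient_id") <- as.character(patient_id)
  attr(out, "technique") <- as.character(technique)
  out
}

# carry metadata from one DVH onto new (dose, volume) columns
rebuild_dvh <- function(template, dose, volume, subclass) {
  new_dvh(dose, volume, subclass,
          attr(template, "structure"),
          attr(template, "total_volume"),
          attr(template, "patient_id"),
          attr(template, "technique"))
}

#' @export
print.dvh <- function(x, ...) {
  kind <- if (inherits(x, "cumulative_dvh")) "cumulative" else "differential"
  meta <- dvh_info(x)
  cat(sprintf("<%s DVH> %s", kind, meta$structure))
  if (!is.na(meta$patient_id)) cat(sprintf(" [%s", meta$patient_id))
  if (!is.na(meta$technique)) cat(sprintf(", %s", meta$technique))
  if (!is.na(meta$patient_id)) cat("]")
  if (!is.na(meta$total_volume)) cat(sprintf(" %.1f cm^3", meta$total_volume))
  cat(sprintf(", %d samples, max dose %.2f Gy\n", nrow(x), max(x$dose)))
  NextMethod()
}

#' Structure metadata of a DVH
#'
#' @param x A DVH object.
#' @return A one-row tibble with `structure`, `patient_id`, `technique`,
#'   `total_volume`.
#' @export
dvh_info <- function(x) {
  stopifnot(inherits(x, "dvh"))
  tibble::tibble(
    structure = attr(x, "structure"),
    patient_id = attr(x, "patient_id"),
    technique = attr(x, "technique"),
    total_volume = attr(x, "total_volume")
  )
}

#' Convert between cumulative and differential DVH form
#'
#' `as_differential()` differences a cumulative DVH: the bin between
#' consecutive dose samples gets the volume lost across it,
#' `v_i = V(d_i) - V(d_{i+1})`, placed at the bin-centre dose; any residual
#' volume still present at the last sample is absorbed into the top bin, so
#' the fractions always sum to one. `as_cumulative()` inverts this: bin
#' edges are reconstructed midway between centres and
#' `V(D) = sum of v_i over bins with centre >= D` is evaluated at the
#' edges. The two maps are mutual inverses on matching grids (to 1e-9).
#'
#' @param x A DVH object.
#' @return The DVH in the requested form.
#' @examples
#' d <- as_differential(cumulative_dvh(c(0, 40, 80), c(1, 0.5, 0)))
#' d$dose    # bin centres 20, 60
#' as_cumulative(d)
#' @export
as_differential <- function(x) UseMethod("as_differential")

#' @export
as_differential.differential_dvh <- function(x) x

#' @export
as_differential.cumulative_dvh <- function(x) {
  if (nrow(x) < 2L) {
    abort_validation("Need at least 2 cumulative samples to difference a DVH.")
  }
  k <- nrow(x)
  v <- -diff(x$volume)
  v[k - 1L] <- v[k - 1L] + x$volume[k]  # residual above the last edge
  centers <- (x$dose[-k] + x$dose[-1L]) / 2
  rebuild_dvh(x, centers, v, "differential_dvh")
}

#' @rdname as_differential
#' @param bin_width Bin width in Gy used to give a single-bin differential
#'   DVH an extent (default 0.1 Gy, a typical planning-system export
#'   resolution).
#' @export
as_cumulative <- function(x, bin_width = 0.1) UseMethod("as_cumulative")

#' @export
as_cumulative.cumulative_dvh <- function(x, bin_width = 0.1) x

#' @export
as_cumulative.differential_dvh <- function(x, bin_width = 0.1) {
  d <- x$dose
  m <- length(d)
  if (m == 1L) {
    inner <- c(d - bin_width / 2, d + bin_width / 2)
  } else {
    mid <- (d[-m] + d[-1L]) / 2
    inner <- c(2 * d[1L] - mid[1L], mid, 2 * d[m] - mid[m - 1L])
  }
  inner[1L] <- max(inner[1L], 0)
  edges <- if (inner[1L] > 0) c(0, inner) else inner
  vol <- vapply(edges, function(e) sum(x$volume[d >= e]), numeric(1))
  rebuild_dvh(x, edges, vol, "cumulative_dvh")
}

#' Resample a cumulative DVH onto a uniform dose grid
#'
#' Linear interpolation of V(D) onto `seq(0, max dose, by = bin_width)`
#' (the grid is extended to cover the maximum dose when it is not a
#' multiple of the bin width). Monotonicity and the total volume are
#' preserved, and resampling is idempotent at a fixed width.
#'
#' @param x A `cumulative_dvh`.
#' @param bin_width Grid spacing in Gy (> 0); default 0.1 Gy.
#' @return A `cumulative_dvh` on the uniform grid.
#' @export
resample_dvh <- function(x, bin_width = 0.1) {
  stopifnot(inherits(x, "cumulative_dvh"))
  if (!is_scalar_number(bin_width) || bin_width <= 0) {
    abort_validation("`bin_width` must be a positive number.")
  }
  dmax <- max(x$dose)
  n_bins <- ceiling(dmax / bin_width - 1e-9)
  grid <- seq(0, by = bin_width, length.out = n_bins + 1L)
  if (grid[length(grid)] < dmax - 1e-12) grid <- c(grid, dmax)
  v <- stats::approx(x$dose, x$volume, xout = grid, rule = 2)$y
  v <- pmin(1, pmax(0, cummin(v)))
  rebuild_dvh(x, grid, v, "cumulative_dvh")
}
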