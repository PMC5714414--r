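#' Read and write DVH files
#'
#' The on-disk format is a plain-text CSV dialect: `#`-prefixed header
#' lines carrying `key=value` pairs, then two comma-separated columns
#' `dose,volume`, one structure per file. Recognised header keys:
#'
#' * `structure`, `patient_id`, `technique` - labels.
#' * `total_volume_cm3` - absolute structure volume (needed when volumes
#'   are stored in cm^3).
#' * `dose_unit` - `Gy` (default) or `cGy`; cGy is converted on read.
#' * `volume_type` - `cumulative` or `differential`.
#' * `volume_unit` - `fraction` (default), `percent`, or `cm3`.
#'
#' `read_dvh()` validates the parsed curve (monotone cumulative volumes,
#' strictly increasing doses, no negatives) and reports the offending row
#' on failure. `write_dvh()` emits full-precision values so that a
#' write/read round trip reproduces the DVH to better than 1e-9.
#'
#' @param path File path.
#' @return `read_dvh()`: a [cumulative_dvh()] or [differential_dvh()] as
#'   declared by the header. `write_dvh()`: the path, invisibly.
#' @export
read_dvh <- function(path) {
  if (!file.exists(path)) abort_validation("DVH file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- grepl("^\\s*#", lines)
  hdr_block <- cumsum(!is_hdr) == 0
  header <- parse_dvh_header(lines[hdr_block], path)
  body <- lines[!hdr_block]
  body <- body[nzchar(trimws(body))]
  if (length(body) && grepl("^\\s*dose\\s*,", body[1], ignore.case = TRUE)) {
    body <- body[-1]
  }
  if (!length(body)) abort_validation("No data rows in DVH file %s", path)
  tab <- tryCatch(
    utils::read.csv(text = body, header = FALSE, col.names = c("dose", "volume"),
                    colClasses = "numeric"),
    error = function(e) abort_validation("Malformed data rows in %s: %s", path, conditionMessage(e))
  )
  dose <- tab$dose
  volume <- tab$volume
  if (identical(header$dose_unit, "cGy")) dose <- dose / 100
  total_volume <- header$total_volume_cm3 %||% NA_real_
  volume <- switch(header$volume_unit %||% "fraction",
    fraction = volume,
    percent = volume / 100,
    cm3 = {
      if (is.na(total_volume)) {
        abort_validation("%s stores volumes in cm3 but has no total_volume_cm3 header.", path)
      }
      volume / total_volume
    },
    abort_validation("Unknown volume_unit '%s' in %s", header$volume_unit, path)
  )
  ctor <- switch(header$volume_type,
    cumulative = cumulative_dvh,
    differential = differential_dvh,
    abort_validation("Header volume_type must be 'cumulative' or 'differential' in %s", path)
  )
  withCallingHandlers(
    ctor(dose, volume,
         structure = header$structure %||% "structure",
         total_volume = total_volume,
         patient_id = header$patient_id %||% NA_character_,
         technique = header$technique %||% NA_character_),
    planrad_validation_error = function(e) {
      abort_validation("Invalid DVH in %s: %s", path, conditionMessage(e))
    }
  )
}

parse_dvh_header <- function(lines, path) {
  lines <- sub("^\\s*#\\s*", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) {
    abort_validation("Malformed header line in %s: '%s'", path, lines[bad][1])
  }
  out <- stats::setNames(
    lapply(kv, function(m) trimws(m[3])),
    vapply(kv, function(m) m[2], character(1))
  )
  if (is.null(out$volume_type)) {
    abort_validation("Header of %s lacks the required volume_type key.", path)
  }
  if (!is.null(out$total_volume_cm3)) {
    out$total_volume_cm3 <- suppressWarnings(as.numeric(out$total_volume_cm3))
    if (is.na(out$total_volume_cm3) || out$total_volume_cm3 <= 0) {
      abort_validation("total_volume_cm3 must be a positive number in %s", path)
    }
  }
  out
}

#' @rdname read_dvh
#' @param x A DVH object.
#' @param volume_unit Unit used for the written volume column: `"fraction"`
#'   (default, lossless), `"percent"`, or `"cm3"` (requires a known total
#'   volume).
#' @export
write_dvh <- function(x, path, volume_unit = c("fraction", "percent", "cm3")) {
  stopifnot(inherits(x, "dvh"))
  volume_unit <- match.arg(volume_unit)
  info <- dvh_info(x)
  vol <- switch(volume_unit,
    fraction = x$volume,
    percent = 100 * x$volume,
    cm3 = {
      if (is.na(info$total_volume)) {
        abort_validation("Cannot write cm3 volumes: total_volume is unknown.")
      }
      x$volume * info$total_volume
    }
  )
  hdr <- c(
    paste0("# structure=", info$structure),
    if (!is.na(info$patient_id)) paste0("# patient_id=", info$patient_id),
    if (!is.na(info$technique)) paste0("# technique=", info$technique),
    if (!is.na(info$total_volume)) paste0("# total_volume_cm3=", format_full(info$total_volume)),
    "# dose_unit=Gy",
    paste0("# volume_type=", if (inherits(x, "cumulative_dvh")) "cumulative" else "differential"),
    paste0("# volume_unit=", volume_unit)
  )
  rows <- paste(format_full(x$dose), format_full(vol), sep = ",")
  writeLines(c(hdr, "dose,volume", rows), path)
  invisible(path)
}

#' Read or write a plan manifest
#'
#' A manifest is a JSON file grouping DVH files per patient and technique:
#' `{patient_id: {technique: {"monitor_units": <optional MU>,
#' "structures": {structure: "relative/path.csv"}}}}`. Paths are resolved
#' relative to the manifest's directory.
#'
#' @param path Manifest file path.
#' @return `read_manifest()`: a tibble with one row per structure file
#'   (`patient_id`, `technique`, `structure`, `path`, `monitor_units`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_validation("Manifest not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  rows <- purrr::imap(raw, function(techs, pid) {
    purrr::imap(techs, function(plan, tech) {
      structures <- plan$structures %||% plan
      structures <- structures[names(structures) != "monitor_units"]
      tibble::tibble(
        patient_id = pid,
        technique = tech,
        structure = names(structures),
        path = file.path(base, unlist(structures, use.names = FALSE)),
        monitor_units = as.numeric(plan$monitor_units %||% NA_real_)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (!nrow(out)) abort_validation("Manifest %s lists no structures.", path)
  out
}

#' @rdname read_manifest
#' @param entries A tibble like the one `read_manifest()` returns; `path`
#'   entries must be relative to the manifest location.
#' @export
write_manifest <- function(entries, path) {
  split_p <- split(entries, entries$patient_id)
  obj <- purrr::map(split_p, function(p) {
    purrr::map(split(p, p$technique), function(t) {
      plan <- list(structures = as.list(stats::setNames(t$path, t$structure)))
      if (!all(is.na(t$monitor_units))) {
        plan$monitor_units <- t$monitor_units[!is.na(t$monitor_units)][1]
      }
      plan
    })
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
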