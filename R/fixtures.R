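#' Bundled five-patient prostate VMAT reference summary
#'
#' Summary statistics of a reference cohort of five prostate patients each
#' planned with a single-arc and a double-arc VMAT technique at
#' 78 Gy / 39 fractions: cohort means and sample SDs of the clinical
#' dose-volume criteria plus mean and maximum doses per structure
#' (`prostate_vmat_summary()`), and the per-plan monitor units
#' (`prostate_vmat_mu()`). These serve three roles: worked-example input
#' for the cohort-comparison arithmetic, generation targets for the
#' synthetic-cohort defaults, and per-structure absolute volumes for file
#' fixtures (`prostate_vmat_volumes()`).
#'
#' @return `prostate_vmat_summary()`: a tibble with `technique`,
#'   `structure`, `metric`, `mean`, `sd`. `prostate_vmat_mu()`: a tibble
#'   with `patient_id`, `technique`, `monitor_units`.
#'   `prostate_vmat_volumes()`: a tibble of per-patient structure volumes
#'   in cm^3.
#' @examples
#' percent_change_summary(prostate_vmat_summary())
#' @export
prostate_vmat_summary <- function() {
  single <- tibble::tribble(
    ~structure,         ~metric,  ~mean, ~sd,
    "PTV",              "D99%",   72.5,  0.8,
    "PTV",              "Dmean",  78.3,  0.7,
    "PTV",              "Dmax",   82.7,  0.8,
    "CTV",              "Dmean",  80.1,  0.7,
    "CTV",              "Dmax",   82.6,  0.7,
    "Rectum",           "D30%",   34.7,  6.1,
    "Rectum",           "D50%",   22.3,  4.6,
    "Rectum",           "V35Gy",  29.6,  5.9,
    "Rectum",           "V17Gy",  61.1,  8.5,
    "Rectum",           "Dmean",  28.0,  3.9,
    "Rectum",           "Dmax",   80.1,  0.8,
    "Bladder",          "D30%",   28.3,  8.4,
    "Bladder",          "D50%",   10.6,  6.4,
    "Bladder",          "V35Gy",  25.1,  5.3,
    "Bladder",          "V17Gy",  40.7,  9.8,
    "Bladder",          "Dmean",  22.2,  4.3,
    "Bladder",          "Dmax",   80.7,  1.4,
    "LeftFemoralHead",  "D5%",    31.0,  6.6,
    "LeftFemoralHead",  "Dmean",  16.6,  4.0,
    "LeftFemoralHead",  "Dmax",   40.4,  5.7,
    "RightFemoralHead", "D5%",    28.4,  4.9,
    "RightFemoralHead", "Dmean",  15.8,  1.8,
    "RightFemoralHead", "Dmax",   38.9,  3.8
  )
  double <- tibble::tribble(
    ~structure,         ~metric,  ~mean, ~sd,
    "PTV",              "D99%",   74.6,  0.4,
    "PTV",              "Dmean",  78.7,  0.8,
    "PTV",              "Dmax",   82.8,  0.7,
    "CTV",              "Dmean",  80.3,  0.6,
    "CTV",              "Dmax",   82.9,  0.8,
    "Rectum",           "D30%",   28.5,  6.6,
    "Rectum",           "D50%",   15.9,  3.1,
    "Rectum",           "V35Gy",  25.1,  4.9,
    "Rectum",           "V17Gy",  47.7,  9.0,
    "Rectum",           "Dmean",  25.1,  3.6,
    "Rectum",           "Dmax",   80.1,  0.8,
    "Bladder",          "D30%",   22.2,  7.0,
    "Bladder",          "D50%",   9.2,   3.7,
    "Bladder",          "V35Gy",  20.8,  4.9,
    "Bladder",          "V17Gy",  35.4,  7.8,
    "Bladder",          "Dmean",  20.4,  3.9,
    "Bladder",          "Dmax",   80.7,  1.1,
    "LeftFemoralHead",  "D5%",    41.6,  2.1,
    "LeftFemoralHead",  "Dmean",  24.9,  2.5,
    "LeftFemoralHead",  "Dmax",   49.4,  2.4,
    "RightFemoralHead", "D5%",    39.4,  3.9,
    "RightFemoralHead", "Dmean",  21.1,  3.8,
    "RightFemoralHead", "Dmax",   47.1,  5.8
  )
  dplyr::bind_rows(
    dplyr::mutate(single, technique = "single-arc"),
    dplyr::mutate(double, technique = "double-arc")
  ) |>
    dplyr::select("technique", "structure", "metric", "mean", "sd")
}

#' @rdname prostate_vmat_summary
#' @export
prostate_vmat_mu <- function() {
  tibble::tibble(
    patient_id = rep(sprintf("pt%02d", 1:5), times = 2),
    technique = rep(c("single-arc", "double-arc"), each = 5),
    monitor_units = c(550, 519, 471, 600, 540,
                      598, 676, 587, 610, 730)
  )
}

#' @rdname prostate_vmat_summary
#' @export
prostate_vmat_volumes <- function() {
  tibble::tribble(
    ~patient_id, ~Prostate, ~PTV,  ~Rectum, ~Bladder, ~LeftFemoralHead, ~RightFemoralHead,
    "pt01",      29.0,      107.0, 42.3,    182.5,    146.6,            153.4,
    "pt02",      39.7,      134.1, 110.1,   379.5,    190.4,            189.0,
    "pt03",      54.8,      170.4, 80.1,    552.6,    201.4,            246.0,
    "pt04",      57.3,      176.7, 50.2,    243.9,    199.7,            193.7,
    "pt05",      68.1,      196.1, 76.8,    184.5,    180.0,            198.2
  )
}
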