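# Builders for DVH fixtures used across the suite.

# The worked toy cumulative DVH: flat to 40 Gy, then piecewise-linear
# fall-off reaching zero volume at 80 Gy.
toy_cumulative <- function() {
  cumulative_dvh(c(0, 40, 60, 78, 80), c(1, 1, 0.8, 0.3, 0))
}

# Random valid cumulative DVH on a uniform grid, strictly decreasing
# after dose 0 and reaching zero volume at the top edge.
random_uniform_cumulative <- function(n_bins = sample(5:40, 1),
                                      bin_width = stats::runif(1, 0.2, 3)) {
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  v <- c(1, sort(stats::runif(n_bins - 1, 0.001, 0.999), decreasing = TRUE), 0)
  cumulative_dvh(edges, v)
}

# Uniform partial-volume differential DVH: fraction v at `dose`, the rest
# unirradiated.
partial_volume_dvh <- function(dose, v) {
  if (v >= 1) differential_dvh(dose, 1) else differential_dvh(c(0, dose), c(1 - v, v))
}

# Scale every bin dose of a differential DVH by a constant factor.
rescale_doses <- function(d, factor) {
  differential_dvh(d$dose * factor, d$volume,
                   structure = attr(d, "structure"))
}

# A tiny two-patient, two-technique record set with constant metrics.
constant_records <- function(value = 10) {
  tidyr::expand_grid(patient_id = c("a", "b"),
                     technique = c("single-arc", "double-arc"),
                     structure = "Rectum", metric = "D50%") |>
    dplyr::mutate(value = value)
}
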