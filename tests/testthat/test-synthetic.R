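test_that("generated target DVHs realise the requested coverage and maximum", {
  ptv <- generate_target_dvh(d99 = 74.6, dmax = 82.8)
  expect_lt(abs(dose_at_volume(ptv, 99) - 74.6), 0.05)
  expect_equal(max_dose(ptv), 82.8)
  expect_equal(ptv$volume[1], 1)
  expect_true(all(diff(ptv$volume) <= 0))

  # near-degenerate fall-off approaches a step at the coverage dose
  steep <- generate_target_dvh(d99 = 74.6, dmax = 74.8, bin_width = 0.01)
  expect_lt(abs(dose_at_volume(steep, 50) - 74.65), 0.1)
  expect_error(generate_target_dvh(d99 = 80, dmax = 78),
               class = "planrad_infeasible_error")
})

test_that("overlap OAR DVHs hit the configured V17/V35 and stay monotone", {
  rectum <- generate_oar_dvh("overlap_oar", v17 = 61.1, v35 = 29.6,
                             overlap_dose = 79.8, structure = "Rectum")
  expect_lt(abs(volume_at_dose(rectum, 17) - 61.1), 0.1)
  expect_lt(abs(volume_at_dose(rectum, 35) - 29.6), 0.1)
  expect_true(all(diff(rectum$volume) <= 1e-12))
  # a rectum-like curve keeps V35Gy inside the clinically observed band
  expect_gt(volume_at_dose(rectum, 35), 20)
  expect_lt(volume_at_dose(rectum, 35), 36)

  # V35Gy is steerable: larger targets give strictly larger measured values
  v35s <- c(18, 22, 26, 30, 34)
  measured <- vapply(v35s, function(v) {
    volume_at_dose(generate_oar_dvh("overlap_oar", v17 = 50, v35 = v,
                                    overlap_dose = 80), 35)
  }, numeric(1))
  expect_true(all(diff(measured) > 0))

  expect_error(generate_oar_dvh("overlap_oar", v17 = 30, v35 = 40,
                                overlap_dose = 80),
               class = "planrad_infeasible_error")
  expect_error(generate_oar_dvh("overlap_oar", v17 = 61.1, v35 = 29.6,
                                overlap_dose = 80, tail_shape = 0.8,
                                adapt_tail = FALSE),
               class = "planrad_infeasible_error")
})

test_that("lateral OAR DVHs realise D5% and maximum dose without target overlap", {
  fem <- generate_oar_dvh("lateral_oar", d5 = 31, dmax = 40.4,
                          structure = "LeftFemoralHead")
  expect_lt(abs(dose_at_volume(fem, 5) - 31), 0.05)
  expect_equal(max_dose(fem), 40.4)
  expect_lt(max_dose(fem), 70)  # no overlap: far below prescription
  expect_error(generate_oar_dvh("lateral_oar", d5 = 45, dmax = 40),
               class = "planrad_infeasible_error")
})

test_that("cohort generation is deterministic and byte-identical under a seed", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  generate_cohort(cohort_config(n_patients = 2, seed = 77), dir = dir1)
  generate_cohort(cohort_config(n_patients = 2, seed = 77), dir = dir2)
  files <- list.files(dir1, recursive = TRUE)
  expect_gt(length(files), 0)
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
  other <- generate_cohort(cohort_config(n_patients = 2, seed = 78))
  first <- generate_cohort(cohort_config(n_patients = 2, seed = 77))
  expect_false(identical(first$dvhs$dvh[[1]]$volume, other$dvhs$dvh[[1]]$volume))
})

test_that("a singleton cohort is valid and the summary declines an SD", {
  coh <- generate_cohort(cohort_config(n_patients = 1, seed = 5))
  expect_equal(nrow(coh$plans), 2)
  expect_true(all(is.na(coh$plans$monitor_units)))
  recs <- plan_records(coh)
  s <- cohort_summary(recs)
  expect_true(all(is.na(s$sd)))
  expect_true(all(s$n == 1))
})

test_that("generate-then-measure recovers sampled targets across 200 draws", {
  set.seed(20260924)
  n_draws <- 200
  ok_d99 <- ok_v35 <- logical(n_draws)
  for (i in seq_len(n_draws)) {
    d99 <- stats::rnorm(1, 74.6, 0.4)
    dmax <- stats::rnorm(1, 82.8, 0.7)
    if (dmax < d99 + 0.5) dmax <- d99 + 0.5
    ptv <- generate_target_dvh(d99, dmax)
    ok_d99[i] <- abs(dose_at_volume(ptv, 99) - d99) <= 0.1

    v17 <- min(max(stats::rnorm(1, 61.1, 8.5), 1), 99)
    v35 <- min(max(stats::rnorm(1, 29.6, 5.9), 0.5), v17 - 1)
    oar <- generate_oar_dvh("overlap_oar", v17 = v17, v35 = v35,
                            overlap_dose = stats::rnorm(1, 79.8, 0.5))
    ok_v35[i] <- abs(volume_at_dose(oar, 35) - v35) <= 1
  }
  expect_gte(mean(ok_d99), 0.95)
  expect_gte(mean(ok_v35), 0.95)
})

test_that("the default cohort reproduces every expected technique contrast", {
  coh <- generate_cohort(cohort_config(seed = 1))
  rep <- cmd_compare(coh)
  s <- tidy(rep)
  ch <- function(st, m) s$percent_change[s$structure == st & s$metric == m]
  # rectum and bladder dose-volume criteria improve under double-arc
  for (st in c("Rectum", "Bladder")) {
    for (m in c("D30%", "D50%", "V17Gy", "V35Gy")) expect_lt(ch(st, m), 0)
  }
  # femoral heads pay the price; PTV coverage improves; MU increases
  expect_gt(ch("LeftFemoralHead", "D5%"), 0)
  expect_gt(ch("RightFemoralHead", "D5%"), 0)
  expect_gt(ch("PTV", "D99%"), 0)
  expect_gt(ch("Plan", "MU"), 0)

  # rectal NTCP is higher for the technique whose overlap region runs hotter
  rb <- plan_radiobiology(coh) |>
    tidyr::pivot_wider(id_cols = "patient_id", names_from = "technique",
                       values_from = "ntcp")
  expect_true(all(rb$`double-arc` > rb$`single-arc`))
})
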