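test_that("dose_at_volume inverts the cumulative curve by linear interpolation", {
  c1 <- toy_cumulative()
  # between (60 Gy, 80%) and (78 Gy, 30%): 60 + (80-50)/(80-30) * 18
  expect_equal(dose_at_volume(c1, 50), 70.8, tolerance = 1e-12)
  # leading plateau at 100%: the minimum dose, where coverage is first lost
  expect_equal(dose_at_volume(c1, 100), 40)
  # exact interior flat run returns its lower dose
  flat <- cumulative_dvh(c(0, 30, 50, 70), c(1, 0.5, 0.5, 0))
  expect_equal(dose_at_volume(flat, 50), 30)
  expect_error(dose_at_volume(c1, 0), class = "planrad_validation_error")
  expect_error(dose_at_volume(c1, 101), class = "planrad_validation_error")
})

test_that("volume_at_dose interpolates and handles the boundaries", {
  c1 <- toy_cumulative()
  expect_equal(volume_at_dose(c1, 35), 100)
  # between (60, 80%) and (78, 30%): 80 - (9/18)*50
  expect_equal(volume_at_dose(c1, 69), 55, tolerance = 1e-12)
  expect_equal(volume_at_dose(c1, 0), 100)
  expect_equal(volume_at_dose(c1, 95), 0)
  expect_error(volume_at_dose(c1, -1), class = "planrad_validation_error")
})

test_that("mean_dose is the volume-weighted bin mean, independent of representation", {
  expect_equal(mean_dose(differential_dvh(c(20, 60), c(0.5, 0.5))), 40)
  uni <- cumulative_dvh(c(0, 78, 78.1), c(1, 1, 0))
  expect_equal(mean_dose(uni), 78.05)
  set.seed(7)
  for (i in 1:10) {
    c1 <- random_uniform_cumulative()
    bw <- diff(c1$dose)[1]
    expect_lt(abs(mean_dose(c1) - mean_dose(as_differential(c1))), 1e-12)
    back <- as_cumulative(as_differential(c1))
    expect_lt(abs(mean_dose(c1) - mean_dose(back)), bw / 2)
  }
})

test_that("max_dose finds the dose where volume crosses epsilon", {
  expect_equal(max_dose(toy_cumulative()), 80)
  expect_equal(max_dose(cumulative_dvh(c(0, 78), c(1, 1))), 78)
  # 2% at 78 Gy falling to 0.5% at 80 Gy: the 1% level is crossed at
  # 78 + (0.02-0.01)/(0.02-0.005) * 2
  tail <- cumulative_dvh(c(0, 78, 80, 83), c(1, 0.02, 0.005, 0))
  expect_equal(max_dose(tail, epsilon_volume = 0.01), 78 + 2 / 1.5, tolerance = 1e-12)
  expect_equal(max_dose(tail), 83)
})

test_that("criteria evaluation reports measured values and pass/fail", {
  low <- cumulative_dvh(c(0, 72.5, 83), c(1, 0.99, 0), structure = "PTV")
  high <- cumulative_dvh(c(0, 74.6, 83), c(1, 0.99, 0), structure = "PTV")
  crit <- tibble::tibble(metric = "D99%", comparator = ">=", threshold = 74.1)
  r_low <- evaluate_criteria(low, crit)
  r_high <- evaluate_criteria(high, crit)
  expect_false(r_low$pass)
  expect_equal(r_low$measured, 72.5)
  expect_true(r_high$pass)
  expect_equal(r_high$measured, 74.6)

  empty <- evaluate_criteria(low, tibble::tibble(metric = character(),
                                                 comparator = character(),
                                                 threshold = numeric()))
  expect_equal(nrow(empty), 0)
  expect_error(
    evaluate_criteria(low, tibble::tibble(metric = "D99%", comparator = "<",
                                          threshold = 74.1)),
    class = "planrad_validation_error")
})

test_that("Dx and VxGy are monotone and near-inverse on strictly decreasing curves", {
  set.seed(21)
  for (i in 1:10) {
    c1 <- random_uniform_cumulative()
    xs <- sort(stats::runif(8, 1, 99))
    dx <- dose_at_volume(c1, xs)
    expect_true(all(diff(dx) <= 1e-9))                 # non-increasing in x
    ds <- sort(stats::runif(8, 0, max(c1$dose)))
    vx <- volume_at_dose(c1, ds)
    expect_true(all(diff(vx) <= 1e-9))                 # non-increasing in d
    expect_true(all(volume_at_dose(c1, dx) >= xs - 1e-6))
    expect_true(all(mean_dose(c1) <= max_dose(c1) + 1e-12))
  }
})

test_that("interpolated metrics agree with a fine-grid brute-force lookup", {
  set.seed(33)
  for (i in 1:5) {
    c1 <- random_uniform_cumulative(n_bins = sample(5:15, 1))
    fine <- resample_dvh(c1, 0.001)
    for (x in c(5, 30, 50, 99)) {
      brute <- fine$dose[which(fine$volume <= x / 100)[1]]
      expect_lt(abs(dose_at_volume(c1, x) - brute), 0.001 + 1e-9)
    }
    for (d in stats::runif(3, 0, max(c1$dose))) {
      brute <- 100 * fine$volume[which.min(abs(fine$dose - d))]
      expect_lt(abs(volume_at_dose(c1, d) - brute), 0.5)
    }
  }
})
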