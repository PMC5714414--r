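test_that("DVH CSV files parse with unit conversion and validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# structure=PTV", "# volume_type=cumulative",
               "# volume_unit=percent", "dose,volume",
               "0,100", "78,30", "80,0"), path)
  d <- read_dvh(path)
  expect_s3_class(d, "cumulative_dvh")
  expect_equal(nrow(d), 3)
  expect_equal(d$volume[1], 1)

  writeLines(c("# structure=PTV", "# volume_type=differential",
               "dose,volume", "20,0.4", "60,0.6"), path)
  d2 <- read_dvh(path)
  expect_s3_class(d2, "differential_dvh")
  expect_equal(sum(d2$volume), 1)

  # cGy doses and absolute cm3 volumes are normalised using the header
  writeLines(c("# structure=Rectum", "# total_volume_cm3=42.3",
               "# dose_unit=cGy", "# volume_type=cumulative",
               "# volume_unit=cm3", "dose,volume",
               "0,42.3", "4000,21.15", "8000,0"), path)
  d3 <- read_dvh(path)
  expect_equal(d3$dose, c(0, 40, 80))
  expect_equal(d3$volume, c(1, 0.5, 0))
  expect_equal(dvh_info(d3)$total_volume, 42.3)
})

test_that("invalid DVH files are rejected with the offending row named", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# volume_type=cumulative", "# volume_unit=percent",
               "dose,volume", "0,100", "40,30", "60,40", "80,0"), path)
  expect_error(read_dvh(path), "row 3", class = "planrad_validation_error")

  writeLines(c("# volume_type=cumulative", "dose,volume",
               "0,1", "50,0.5", "50,0.4"), path)
  expect_error(read_dvh(path), "strictly increasing",
               class = "planrad_validation_error")

  writeLines(c("dose,volume", "0,1"), path)
  expect_error(read_dvh(path), "volume_type", class = "planrad_validation_error")
})

test_that("write/read round trip is lossless for both DVH types", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(11)
  for (i in 1:5) {
    c1 <- random_uniform_cumulative()
    attr(c1, "total_volume") <- 42.3
    write_dvh(c1, path)
    expect_true(any(grepl("total_volume_cm3=42.3", readLines(path))))
    back <- read_dvh(path)
    expect_lt(max(abs(back$dose - c1$dose)), 1e-9)
    expect_lt(max(abs(back$volume - c1$volume)), 1e-9)
  }
  d1 <- differential_dvh(c(20, 60), c(0.4, 0.6), structure = "Rectum")
  write_dvh(d1, path)
  expect_true(any(grepl("volume_type=differential", readLines(path))))
  back <- read_dvh(path)
  expect_s3_class(back, "differential_dvh")
  expect_equal(back$volume, d1$volume, tolerance = 1e-12)
})

test_that("cumulative-to-differential differencing matches hand results", {
  d <- as_differential(cumulative_dvh(c(0, 40, 80), c(1, 0.5, 0)))
  expect_equal(d$dose, c(20, 60))
  expect_equal(d$volume, c(0.5, 0.5))

  # a uniform-dose structure collapses into the top bin
  u <- as_differential(cumulative_dvh(c(0, 70, 70.1), c(1, 1, 0)))
  expect_equal(u$volume, c(0, 1))
  expect_equal(u$dose[2], 70.05)

  expect_error(as_differential(cumulative_dvh(0, 1)), "at least 2",
               class = "planrad_validation_error")
})

test_that("differential-to-cumulative inverts the differencing", {
  d <- differential_dvh(c(20, 60), c(0.5, 0.5))
  c1 <- as_cumulative(d)
  expect_equal(c1$dose, c(0, 40, 80))
  expect_equal(c1$volume, c(1, 0.5, 0))

  step <- as_cumulative(differential_dvh(70, 1))
  expect_equal(step$volume[1], 1)
  expect_equal(step$volume[length(step$volume)], 0)
  expect_equal(mean_dose(step), 70, tolerance = 1e-9)
})

test_that("conversion conserves volume and round-trips on uniform grids", {
  set.seed(4711)
  for (i in 1:25) {
    c1 <- random_uniform_cumulative()
    d <- as_differential(c1)
    expect_true(all(d$volume >= 0))
    expect_lt(abs(sum(d$volume) - 1), 1e-9)
    back <- as_cumulative(d)
    expect_equal(back$dose, c1$dose, tolerance = 1e-12)
    expect_lt(max(abs(back$volume - c1$volume)), 1e-9)
  }
})

test_that("resampling interpolates linearly, preserves monotonicity, and is idempotent", {
  c1 <- cumulative_dvh(c(0, 80), c(1, 0))
  r <- resample_dvh(c1, 40)
  expect_equal(r$dose, c(0, 40, 80))
  expect_equal(r$volume[2], 0.5)

  same <- resample_dvh(toy_cumulative(), 2)
  expect_equal(dose_at_volume(same, 50), 70.8, tolerance = 1e-9)

  expect_error(resample_dvh(c1, 0), class = "planrad_validation_error")

  set.seed(99)
  for (i in 1:10) {
    c2 <- random_uniform_cumulative()
    w <- stats::runif(1, 0.1, 5)
    once <- resample_dvh(c2, w)
    twice <- resample_dvh(once, w)
    expect_equal(twice$dose, once$dose)
    expect_equal(twice$volume, once$volume, tolerance = 1e-12)
    expect_true(all(diff(once$volume) <= 1e-12))
  }
})
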