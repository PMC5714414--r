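test_that("logistic TCP parameters follow the D50/gamma50 relations", {
  p <- tcp_params(67.5, 2)
  expect_equal(p$q, 4 * 2 / 67.5, tolerance = 1e-15)
  expect_equal(p$p, -8)
  expect_equal(p$p + p$q * p$d50, 0, tolerance = 1e-12)
  expect_equal(tcp_uniform(67.5, p), 0.5, tolerance = 1e-15)

  # normalised slope at D50 recovered by finite differences
  for (pars in list(tcp_params(67.5, 2), tcp_params(50, 1.3), tcp_params(80, 3.5))) {
    h <- 1e-4
    slope <- (tcp_uniform(pars$d50 + h, pars) - tcp_uniform(pars$d50 - h, pars)) / (2 * h)
    expect_equal(pars$d50 * slope, pars$gamma50, tolerance = 1e-6)
  }
  expect_error(tcp_params(-1, 2), class = "planrad_validation_error")
})

test_that("uniform-dose TCP matches direct logistic evaluation", {
  pars <- tcp_params(67.5, 2)
  # independent arithmetic: 1 / (1 + exp(-(p + q * 78)))
  lin <- -8 + (8 / 67.5) * 78
  expect_equal(tcp_uniform(78, pars), 1 / (1 + exp(-lin)), tolerance = 1e-12)
  expect_equal(tcp_uniform(78, pars), 0.776337, tolerance = 1e-6)
  expect_gt(tcp_uniform(0, pars), 0)
  expect_lt(tcp_uniform(0, pars), 0.5)
  expect_false(is.nan(tcp_uniform(0, tcp_params(67.5, 200))))
})

test_that("DVH TCP is the volume-weighted tumorlet product", {
  pars <- tcp_params(67.5, 2)
  uni <- differential_dvh(78, 1)
  expect_equal(tcp(uni, pars), tcp_uniform(78, pars), tolerance = 1e-12)
  halves <- differential_dvh(c(78 - 1e-9, 78), c(0.5, 0.5))
  expect_equal(tcp(halves, pars), tcp_uniform(78, pars), tolerance = 1e-6)

  two <- differential_dvh(c(70, 80), c(0.5, 0.5))
  oracle <- tcp_uniform(70, pars)^0.5 * tcp_uniform(80, pars)^0.5
  expect_equal(tcp(two, pars), oracle, tolerance = 1e-12)
})

test_that("refining a DVH bin at constant dose leaves TCP unchanged", {
  pars <- tcp_params(67.5, 2)
  coarse <- differential_dvh(c(60, 75), c(0.3, 0.7))
  fine <- differential_dvh(c(60 - 1e-9, 60, 75 - 1e-9, 75),
                           c(0.1, 0.2, 0.35, 0.35))
  expect_equal(tcp(fine, pars), tcp(coarse, pars), tolerance = 1e-9)
})

test_that("Kutcher-Burman effective volume reduces the DVH correctly", {
  expect_equal(effective_volume(differential_dvh(63, 1), 0.12)$veff, 1)
  red <- effective_volume(differential_dvh(c(35, 70), c(0.5, 0.5)), 0.12)
  expect_equal(red$d_ref, 70)
  expect_equal(red$veff, 0.5 + 0.5 * 0.5^(1 / 0.12), tolerance = 1e-12)
  # dose-ratio invariance
  scaled <- effective_volume(differential_dvh(1.3 * c(35, 70), c(0.5, 0.5)), 0.12)
  expect_equal(scaled$veff, red$veff, tolerance = 1e-12)
})

test_that("LKB NTCP reproduces analytic fixed points", {
  pars <- lkb_params(80, 0.15, 0.12)
  whole <- ntcp(differential_dvh(80, 1), pars)
  expect_equal(whole$t, 0)
  expect_equal(whole$ntcp, 0.5)

  half <- ntcp(partial_volume_dvh(70, 0.5), pars)
  td50_half <- 80 * 0.5^(-0.12)
  expect_equal(half$td50_v, td50_half, tolerance = 1e-12)
  expect_equal(half$t, (70 - td50_half) / (0.15 * td50_half), tolerance = 1e-12)
  expect_equal(half$ntcp, stats::pnorm(half$t))
  expect_equal(round(half$t, 3), -1.299)
  expect_equal(half$ntcp, 0.097, tolerance = 1e-3)

  d <- differential_dvh(c(30, 55, 78), c(0.5, 0.3, 0.2))
  expect_gt(ntcp(as_cumulative(rescale_doses(d, 1.1)))$ntcp, ntcp(d)$ntcp)
})

test_that("KB reduction equals the closed-form Lyman model on uniform partial volumes", {
  set.seed(5)
  pars <- lkb_params()
  for (i in 1:20) {
    v <- stats::runif(1, 0.05, 1)
    dose <- stats::runif(1, 20, 100)
    via_dvh <- ntcp(partial_volume_dvh(dose, v), pars)
    expect_equal(via_dvh$veff, v, tolerance = 1e-12)
    expect_equal(via_dvh$ntcp, lyman_ntcp_uniform(dose, v, pars), tolerance = 1e-12)
  }
})

test_that("NTCP shows the volume effect below TD50 and degrades gracefully", {
  pars <- lkb_params()
  fracs <- c(0.9, 0.6, 0.3, 0.1)
  probs <- vapply(fracs, function(v) ntcp(partial_volume_dvh(70, v), pars)$ntcp,
                  numeric(1))
  expect_true(all(diff(probs) < 0))  # smaller irradiated fraction, lower NTCP

  cold <- ntcp(differential_dvh(0, 1), pars)
  expect_true(cold$degenerate)
  expect_equal(cold$ntcp, 0)
  expect_s3_class(tidy(cold), "tbl_df")
})

test_that("TCP and NTCP stay in [0,1] and increase under dose escalation", {
  set.seed(13)
  for (i in 1:10) {
    c1 <- random_uniform_cumulative()
    tv <- tcp(c1)
    nv <- ntcp(c1)$ntcp
    expect_true(tv >= 0 && tv <= 1)
    expect_true(nv >= 0 && nv <= 1)
    up <- rescale_doses(as_differential(c1), 1.15)
    expect_gt(tcp(up), tv)
    expect_gt(ntcp(up)$ntcp, nv)
  }
})

test_that("normal_cdf matches the quadrature of the Gaussian density", {
  expect_equal(normal_cdf(0), 0.5)
  q196 <- stats::integrate(stats::dnorm, -Inf, 1.96, rel.tol = 1e-13)$value
  expect_equal(normal_cdf(1.96), q196, tolerance = 1e-10)
  expect_equal(round(normal_cdf(1.96), 6), 0.975002)
  set.seed(2)
  t <- stats::runif(20, -8, 8)
  expect_true(all(abs(normal_cdf(t) + normal_cdf(-t) - 1) < 1e-12))
  expect_error(normal_cdf(Inf), class = "planrad_validation_error")
})

test_that("model parameter files load with defaults for missing entries", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"ntcp": {"td50_1": 76.9, "m": 0.13}}', path)
  p <- read_model_params(path)
  expect_equal(p$ntcp$td50_1, 76.9)
  expect_equal(p$ntcp$m, 0.13)
  expect_equal(p$ntcp$n, 0.12)
  expect_equal(p$tcp$d50, 67.5)

  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("tcp:", "  d50: 70", "  gamma50: 1.8"), ypath)
  expect_equal(read_model_params(ypath)$tcp$d50, 70)
})
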