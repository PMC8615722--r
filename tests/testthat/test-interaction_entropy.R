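test_that("scan_windows and select_window find the quiet regime", {
  # constant series -> all RMSF zero; tie broken by earliest start
  const <- energy_series(0:99, rep(-60, 100))
  sc <- scan_windows(const, 10)
  expect_true(all(sc$rmsf == 0))
  expect_equal(select_window(sc)$start_time, 0)

  # white noise: window RMSF concentrates near sigma
  s <- gen_energy_series(series_spec(n_points = 2e4, sigma = 2, seed = 3))
  sc2 <- scan_windows(s, 1e4)
  expect_lt(abs(sc2$rmsf[1] - 2) / 2, 0.03)

  # two-regime series: minimum lies in the low-sigma regime
  sp <- series_spec(n_points = 2000, sigma = 1, regime_changes = list(
    list(start_index = 1, mean = -60, sigma = 5),
    list(start_index = 1001, mean = -60, sigma = 1)), seed = 10)
  sel <- select_window(scan_windows(gen_energy_series(sp), 500))
  expect_gte(sel$start_idx, 1001)

  expect_error(scan_windows(const, 1000), "longer")
})

test_that("filter_outliers implements the single-pass k-sigma rule", {
  g <- gen_energy_series(series_spec(n_points = 1e5, mean = -60, sigma = 2,
                                     seed = 12))
  f <- filter_outliers(g, 3)
  frac <- f$n_discarded / 1e5
  expect_gt(frac, 0.001); expect_lt(frac, 0.005)

  # a single 10-sigma point is exactly what gets discarded (background is a
  # +/-1 square wave, so nothing else comes near 3 SD)
  x <- energy_series(0:200, c(rep(c(-1, 1), 100), 10))
  f2 <- filter_outliers(x, 3)
  expect_equal(f2$n_discarded, 1L)
  expect_false(10 %in% f2$series$values)

  # constant series: SD = 0 convention keeps everything
  const <- energy_series(0:199, rep(-5, 200))
  expect_equal(filter_outliers(const)$n_discarded, 0L)
})

test_that("ie_entropy: degenerate cases, Jensen bound, invariances", {
  const <- energy_series(0:199, rep(-60, 200))
  expect_identical(ie_entropy(const)$minus_t_delta_s, 0)

  s <- gen_energy_series(series_spec(n_points = 5000, mean = -60, sigma = 1.3,
                                     autocorrelation_time = 3, seed = 6))
  r <- ie_entropy(s)
  expect_gte(r$minus_t_delta_s, 0)

  # translation invariance to 1e-9
  s2 <- energy_series(s$times, s$values + 123.456)
  expect_equal(ie_entropy(s2)$minus_t_delta_s, r$minus_t_delta_s,
               tolerance = 1e-9)

  # convergence trace ends at the final estimate
  tr <- r$convergence_trace
  expect_equal(tr$estimate[nrow(tr)], r$minus_t_delta_s)
  expect_error(ie_entropy(energy_series(1:50, rnorm(50))), "100")
})

test_that("ie_entropy recovers the Gaussian closed form sigma^2 / 2kT", {
  kT <- KB * 300
  for (sg in c(0.5, 1)) {
    s <- gen_energy_series(series_spec(n_points = 1e5, mean = -60, sigma = sg,
                                       seed = 100 + round(10 * sg)))
    exact <- sg^2 / (2 * kT)
    # lognormal delta-method MC error of the exponential average
    tol <- 3 * kT * exp((sg / kT)^2 / 2) / sqrt(1e5) + 0.01
    expect_lt(abs(ie_entropy(s)$minus_t_delta_s - exact), tol)
  }
})

test_that("filtering does not worsen contaminated-Gaussian estimates", {
  kT <- KB * 300
  sg <- 0.8
  exact <- sg^2 / (2 * kT)
  s <- gen_energy_series(series_spec(n_points = 5e4, mean = -60, sigma = sg,
                                     outlier_fraction = 0.005,
                                     outlier_scale = 8, seed = 77))
  raw <- ie_entropy(s)$minus_t_delta_s
  flt <- ie_entropy(filter_outliers(s, 3)$series)$minus_t_delta_s
  expect_lte(abs(flt - exact), abs(raw - exact))
})

test_that("binding_free_energy and average_and_ddg reproduce the worked rows", {
  expect_equal(binding_free_energy(-62.4, 33.8)$dg, -28.6)
  expect_equal(binding_free_energy(-67.7, 33.3)$dg, -34.4)
  expect_equal(binding_free_energy(-50, 0)$dg, -50)

  expect_equal(round(average_and_ddg(c(-28.6, -25.2, -29.2))$wild_avg, 1),
               -27.7)
  res <- average_and_ddg(wild = c(-27.7), mutant = c(-29.9))
  expect_equal(res$ddg, -2.2)
  expect_equal(average_and_ddg(c(-30.6))$wild_avg, -30.6)
})

test_that("ie workflow pieces compose; bootstrap SD is finite", {
  sp <- series_spec(n_points = 6000, mean = -60, sigma = 1.2,
                    outlier_fraction = 0.003, seed = 15)
  r <- ie_analysis(gen_energy_series(sp), window_length = 2000)
  expect_gte(r$minus_t_delta_s, 0)
  expect_equal(r$n_used + r$n_discarded, 2000)

  bs <- ie_bootstrap_sd(gen_energy_series(sp), n_blocks = 50, n_boot = 50)
  expect_true(is.finite(bs) && bs >= 0)
})
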