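test_that("annual series averages paired values only", {
  d <- data.frame(year = c(1991, 1991, 1992, 1992, 1992),
                  observed = c(10, 12, 11, 13, NA),
                  reconstructed = c(9, 11, 10, 14, 99))
  a <- annual_series(d)
  expect_equal(a$observed, c(11, 12))
  expect_equal(a$reconstructed, c(10, 12))
  expect_equal(a$n, c(2L, 2L))
  # reconstruction identical to observation: identical series
  d2 <- data.frame(year = rep(1991:1993, each = 4), observed = rnorm(12))
  d2$reconstructed <- d2$observed
  a2 <- annual_series(d2)
  expect_equal(a2$observed, a2$reconstructed)
})

test_that("per-year lag series is anchored with bootstrap SEs", {
  set.seed(71)
  d <- data.frame(year = rep(1991:1995, each = 50))
  d$observed <- 10 + 0.2 * (d$year - 1991) + rnorm(250, 0, 0.5)
  d$reconstructed <- 10 + 0.1 * (d$year - 1991) + rnorm(250, 0, 0.5)
  ls <- annual_lag_series(d, n_boot = 200, seed = 1)
  expect_equal(ls$lag[1], 0)
  expect_equal(ls$se[1], 0)
  expect_true(all(ls$se[-1] > 0))
  # truth: lag grows by 0.1/yr
  expect_true(all(abs(ls$lag - 0.1 * (ls$year - 1991)) < 3 * ls$se + 1e-9))
  # deterministic under a fixed seed
  expect_identical(ls, annual_lag_series(d, n_boot = 200, seed = 1))
})

test_that("cross-calibration recovers linear and degenerate maps", {
  set.seed(72)
  b <- runif(500, 1, 3)
  cal <- cross_calibrate(2 * b, b)
  grid <- seq(1.2, 2.8, length.out = 20)
  expect_equal(cal$g(grid), 2 * grid, tolerance = 1e-6)
  # constant temperature: constant map
  cal2 <- cross_calibrate(rep(8, 500) + rnorm(500, 0, 1e-6), b)
  expect_lt(diff(range(cal2$g(grid))), 1e-3)
  expect_error(cross_calibrate(2 * b, rep(1, 500)), "degenerate")
  expect_error(cross_calibrate(2 * b[1:50], b[1:50]), "100")
})

test_that("cross-calibration recovers a smooth monotone map within noise", {
  set.seed(73)
  b <- runif(800, 0, 3)
  g0 <- function(v) 6 + 2 * tanh(v - 1.5)
  rec_t <- g0(b) + rnorm(800, 0, 0.3)
  cal <- cross_calibrate(rec_t, b, k = 20)
  grid <- seq(0.3, 2.7, length.out = 40)
  se_pt <- 0.3 / sqrt(800 / 40)        # rough per-window SE
  expect_lt(max(abs(cal$g(grid) - g0(grid))), 3 * se_pt + 0.05)
})

test_that("paired GLS trend fit honours the shared-intercept construction", {
  years <- 1991:2011
  # identical series: zero lag everywhere
  obs <- 10 + 0.05 * (years - 1991)
  f0 <- fit_paired_trend_gls(obs, obs, years, n_boot = 50, seed = 1)
  expect_equal(f0$slope_diff, 0, tolerance = 1e-10)
  expect_equal(f0$lag_final, 0, tolerance = 1e-10)
  # noise-free: obs slope 0.032, rec slope 0 -> lag(2011) = 0.64
  obs2 <- 10 + 0.032 * (years - 1991)
  rec2 <- rep(10, 21)
  f1 <- fit_paired_trend_gls(obs2, rec2, years, n_boot = 50, seed = 1)
  expect_equal(f1$slope_obs, 0.032, tolerance = 1e-10)
  expect_equal(f1$slope_rec, 0, tolerance = 1e-10)
  expect_equal(f1$lag_final, 0.64, tolerance = 1e-10)
  expect_equal(f1$lag_fitted$lag, 0.032 * (years - 1991), tolerance = 1e-10)
  # bootstrap SEs are deterministic given the seed
  f2 <- fit_paired_trend_gls(obs2, rec2, years, n_boot = 50, seed = 1)
  expect_identical(f1$slope_diff_se, f2$slope_diff_se)
  expect_error(fit_paired_trend_gls(obs2[1:4], rec2[1:4], years[1:4]),
               "5 years")
})

test_that("AR1 errors are detected by the structure selection", {
  years <- 1991:2011
  picks <- vapply(1:30, function(seed) {
    set.seed(seed)
    e <- as.numeric(arima.sim(list(ar = 0.7), 21, sd = 0.3))
    obs <- 10 + 0.05 * (years - 1991) + e
    rec <- 10 + 0.02 * (years - 1991) +
      as.numeric(arima.sim(list(ar = 0.7), 21, sd = 0.3))
    f <- fit_paired_trend_gls(obs, rec, years, n_boot = 10, seed = seed)
    grepl("ar1", f$structure)
  }, TRUE)
  expect_gt(mean(picks), 0.5)
})

test_that("iid data selects the simplest error structure", {
  years <- 1991:2011
  picks <- vapply(1:20, function(seed) {
    set.seed(100 + seed)
    obs <- 10 + 0.05 * (years - 1991) + rnorm(21, 0, 0.3)
    rec <- 10 + rnorm(21, 0, 0.3)
    fit_paired_trend_gls(obs, rec, years, n_boot = 10, seed = seed)$structure
  }, "")
  expect_gt(mean(picks == "iid"), 0.5)
})

test_that("net lag trend through the origin is exact on clean input", {
  years <- 1991:2011
  expect_equal(net_lag_trend(rep(0, 21), years, n_boot = 20)$slope, 0,
               tolerance = 1e-12)
  net <- -0.0125 * (years - 1991)
  f <- net_lag_trend(net, years, n_boot = 20)
  expect_equal(f$slope, -0.0125, tolerance = 1e-10)
  expect_equal(f$lag_final, -0.25, tolerance = 1e-9)
  expect_lt(f$p_value, 1e-6)
})

test_that("debt and credit assemble with correct signs and symmetry", {
  years <- 1991:2011
  tt <- years - 1991
  temp <- data.frame(year = years, observed = 10 + 0.05 * tt,
                     reconstructed = 10 + 0.02 * tt)
  # g = identity and BOD series equal to the temperature series:
  # credit must reproduce debt exactly
  acct <- compute_debt_credit(temp, temp, g = identity, n_boot = 30, seed = 2)
  expect_equal(acct$series$credit, acct$series$debt, tolerance = 1e-10)
  expect_equal(acct$series$net, 2 * acct$series$debt, tolerance = 1e-10)
  expect_equal(acct$debt_final, 0.6, tolerance = 1e-9)
  # an improving observed BOD against a flat reconstruction is a credit:
  # negative lag after mapping through an increasing g
  bod <- data.frame(year = years, observed = log(2) - 0.03 * tt,
                    reconstructed = rep(log(2), 21))
  g_up <- function(v) 8 + 2 * v
  acct2 <- compute_debt_credit(temp, bod, g = g_up, n_boot = 30, seed = 3)
  expect_lt(acct2$credit_final, 0)
  expect_equal(acct2$credit_final, 2 * (-0.03) * 20, tolerance = 1e-8)
  expect_equal(acct2$series$net, acct2$series$debt + acct2$series$credit)
})
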