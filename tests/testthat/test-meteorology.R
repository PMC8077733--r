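test_that("vapor pressure is positive, increasing, and matches an independent
           re-derivation of the Magnus formula", {
  grid <- seq(-30, 40, by = 0.5)
  e <- water_vapor_pressure(grid)
  expect_true(all(e > 0))
  expect_true(all(diff(e) > 0))
  expect_gt(water_vapor_pressure(20), water_vapor_pressure(10))
  # second implementation of the same printed constants, via hPa
  magnus_hpa <- function(td) 6.112 * exp(17.62 * td / (243.12 + td))
  expect_equal(e, magnus_hpa(grid) / 10, tolerance = 1e-12)
  expect_error(water_vapor_pressure(NA_real_), "finite")
  expect_error(water_vapor_pressure(80), "plausible")
})

test_that("apparent temperature evaluates the printed affine formula", {
  expect_equal(apparent_temperature(30, 3), 32.9)
  expect_equal(apparent_temperature(0, 0), -1.3)
  expect_equal(apparent_temperature(25, 2), 26.1)
  expect_error(apparent_temperature(Inf, 1), "finite")
})

test_that("daily metrics aggregate hours correctly and respect completeness", {
  h <- make_hourly_day("2000-06-01", dry = 10:33)
  expect_equal(daily_metric(h, heat_metric_spec("T", "MX"))$value, 33)
  expect_equal(daily_metric(h, heat_metric_spec("T", "MN"))$value, 10)
  expect_equal(daily_metric(h, heat_metric_spec("T", "Avg"))$value, 21.5)
  # 17 of 24 hours < default completeness minimum of 18
  h17 <- h[1:17, ]
  expect_true(is.na(daily_metric(h17, heat_metric_spec("T", "MX"))$value))
  expect_false(is.na(daily_metric(h17, heat_metric_spec("T", "MX"),
                                  min_hours = 17)$value))
  expect_equal(nrow(daily_metric(h[0, ], heat_metric_spec("T", "MX"))), 0)
})

test_that("AT daily extremes equal the pointwise transform of T extremes at
           constant humidity (brute-force per-hour recompute)", {
  h <- make_hourly_day("2000-06-01", dry = 10:33, dew = rep(8, 24))
  at_hourly <- apparent_temperature(h$dry_bulb, water_vapor_pressure(8))
  expect_equal(daily_metric(h, heat_metric_spec("AT", "MX"))$value,
               max(at_hourly))
  expect_equal(daily_metric(h, heat_metric_spec("AT", "MN"))$value,
               min(at_hourly))
  # affine in T at fixed e, so the max/min transform commutes
  expect_equal(max(at_hourly),
               apparent_temperature(33, water_vapor_pressure(8)))
})

test_that("percentile thresholds use type-7 interpolation and are monotone", {
  daily <- data.frame(date = as.Date("2000-01-01") + 0:99, value = 1:100)
  expect_equal(percentile_threshold(daily, 95)$value, 95.05)
  # brute-force sort-and-interpolate oracle
  x <- sort(daily$value); hq <- 1 + 0.98 * (length(x) - 1)
  lo <- floor(hq)
  expect_equal(percentile_threshold(daily, 98)$value,
               x[lo] + (hq - lo) * (x[lo + 1] - x[lo]))
  cst <- data.frame(date = daily$date, value = rep(7, 100))
  for (p in c(95, 98, 99)) expect_equal(percentile_threshold(cst, p)$value, 7)
  set.seed(3)
  rnd <- data.frame(date = daily$date, value = rnorm(100))
  th <- sapply(c(95, 98, 99), function(p) percentile_threshold(rnd, p)$value)
  expect_true(all(diff(th) >= 0))
  expect_error(percentile_threshold(daily[1:50, ], 95), "at least 100")
})

test_that("extreme indicators use strict exceedance and nest across
           percentiles", {
  thr <- structure(list(percentile = 95, value = 30, n_basis = 100),
                   class = "threshold_spec")
  d <- data.frame(date = as.Date("2000-06-01") + 0:2,
                  value = c(30, 30.1, NA))
  expect_equal(extreme_indicator(d, thr)$x, c(0L, 1L, NA))
  set.seed(4)
  daily <- data.frame(date = as.Date("2000-01-01") + 0:999,
                      value = rnorm(1000, 25, 5))
  xs <- lapply(c(95, 98, 99), function(p)
    extreme_indicator(daily, percentile_threshold(daily, p))$x)
  expect_true(all(xs[[3]] <= xs[[2]]))   # P99 exceedances subset of P98
  expect_true(all(xs[[2]] <= xs[[1]]))
  # exceedance count ~ (1 - p) N within the quantile convention's off-by-one
  expect_lte(abs(sum(xs[[1]]) - 0.05 * 1000), 1)
})

test_that("lag matrix shifts by calendar day with leading missings", {
  ind <- data.frame(date = as.Date("2000-06-01") + 0:4,
                    x = c(0L, 1L, 0L, 0L, 1L))
  lm <- lag_matrix(ind, max_lag = 2)
  expect_equal(lm$lag0, ind$x)
  expect_equal(lm$lag1, c(NA, 0L, 1L, 0L, 0L))
  expect_equal(lm$lag2, c(NA, NA, 0L, 1L, 0L))
  expect_equal(lag_matrix(ind, max_lag = 0)$lag0, ind$x)
  # brute-force shift oracle on a random series
  set.seed(5)
  ind2 <- data.frame(date = as.Date("2001-01-01") + 0:199,
                     x = rbinom(200, 1, 0.2))
  lm2 <- lag_matrix(ind2, max_lag = 3)
  for (l in 0:3)
    expect_equal(lm2[[paste0("lag", l)]][(l + 1):200], ind2$x[1:(200 - l)])
})

test_that("truncation caps at the threshold and kills the indicator", {
  thr <- structure(list(percentile = 95, value = 35, n_basis = 100),
                   class = "threshold_spec")
  d <- data.frame(date = as.Date("2000-06-01") + 0:1, value = c(40, 30))
  tr <- truncate_at_threshold(d, thr)
  expect_equal(tr$value, c(35, 30))
  expect_true(all(extreme_indicator(tr, thr)$x == 0))
})

test_that("lag 1-3 mean matches a brute-force rolling computation", {
  d <- data.frame(date = as.Date("2000-06-01") + 0:9,
                  value = c(10, 20, 30, rep(5, 7)))
  m <- lag123_mean(d)
  expect_equal(m$value[4], 20)
  expect_true(all(is.na(m$value[1:3])))
  cst <- data.frame(date = d$date, value = rep(3.5, 10))
  expect_equal(lag123_mean(cst)$value[4:10], rep(3.5, 7))
  set.seed(6)
  rv <- data.frame(date = d$date, value = rnorm(10))
  mm <- lag123_mean(rv)
  for (t in 4:10)
    expect_equal(mm$value[t], mean(rv$value[(t - 3):(t - 1)]))
})
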