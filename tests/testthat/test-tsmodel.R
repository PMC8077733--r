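# independent IRLS oracle for Poisson log-link GLM (test-only)
irls_poisson <- function(x, y, tol = 1e-10, maxit = 50) {
  beta <- rep(0, ncol(x)); beta[1] <- log(mean(y) + 0.1)
  for (i in seq_len(maxit)) {
    eta <- drop(x %*% beta); mu <- exp(eta)
    z <- eta + (y - mu) / mu
    w <- mu
    beta_new <- solve(crossprod(x, x * w), crossprod(x, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

test_that("natural cubic bases have the right dimension and reproduce
           linear functions", {
  x <- seq(0, 30, length.out = 200)
  b <- natural_cubic_basis(x, 2)
  expect_equal(ncol(b), 3)
  expect_equal(attr(b, "knots"), c(10, 20))
  # projection oracle: a linear function lies in the span
  fit <- lm.fit(cbind(1, b), 2 + 0.5 * x)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  # linearity beyond the boundary knots: second differences vanish there
  xs <- seq(-10, 40, by = 0.1)
  bs <- natural_cubic_basis(xs, 2, boundary = c(0, 30))
  for (j in 1:3) {
    for (region in list(xs < 0, xs > 30)) {
      d2 <- diff(bs[region, j], differences = 2)
      expect_lt(max(abs(d2)), 1e-8)
    }
  }
  mb <- natural_cubic_basis(1:153, placement = "monthly")
  expect_equal(ncol(mb), 5)
  expect_equal(attr(mb, "knots"), c(32, 62, 93, 124))
  expect_error(natural_cubic_basis(rep(1, 10), 2), "distinct|degenerate")
})

make_design_inputs <- function(n_years = 3, seed = 31) {
  wc <- weather_gen_config(n_years = n_years, seed = seed)
  w <- simulate_hourly_weather(wc)
  daily <- daily_metric(w, heat_metric_spec("AT", "MN"))
  thr <- percentile_threshold(daily, 95)
  covs <- continuous_temp_covariates(daily, dpt = daily_max_dewpoint(w),
                                     threshold = thr)
  warm <- daily$date[is_warm_season(daily$date)]
  set.seed(seed)
  health <- data.frame(date = warm, count = rpois(length(warm), 50),
                       holiday_a = as.integer(format(warm, "%m-%d") == "07-04"),
                       holiday_b = as.integer(format(warm, "%m-%d") == "06-19"),
                       hosp_1 = rbinom(length(warm), 1, 0.95))
  list(health = health, covs = covs, thr = thr)
}

test_that("the design matrix has the documented block structure", {
  inp <- make_design_inputs(3)
  d <- build_design(inp$health, inp$covs)
  expect_length(d$blocks$dow, 6)
  expect_length(d$blocks$year, 2)          # 3 years, first is reference
  expect_length(d$blocks$season_by_year, 15)  # 5 basis cols x 3 years
  expect_length(d$blocks$holiday, 2)
  expect_length(d$blocks$hosp, 1)
  expect_length(d$blocks$temp, 3)
  expect_length(d$blocks$dpt, 3)
  # apparent-temperature exposure run omits the dew-point block
  d2 <- build_design(inp$health, inp$covs, include_dpt = FALSE)
  expect_null(d2$blocks$dpt)
  expect_false(any(grepl("dpt", colnames(d2$x))))
  expect_equal(qr(d$x)$rank, ncol(d$x))
})

test_that("quasi-Poisson fitting matches an independent IRLS implementation
           and recovers no overdispersion from Poisson data", {
  set.seed(32)
  n <- 800
  x <- cbind(1, rnorm(n), rbinom(n, 1, 0.3))
  colnames(x) <- c("(Intercept)", "z", "H")
  mu <- exp(1 + 0.3 * x[, 2] + 0.2 * x[, 3])
  y <- rpois(n, mu)
  design <- structure(list(x = x, y = y,
                           dates = as.Date("2000-05-01") + seq_len(n) - 1,
                           blocks = list(), has_h = TRUE),
                      class = "heat_design")
  fit <- fit_quasipoisson(design)
  expect_equal(unname(fit$coefficients), unname(irls_poisson(x, y)),
               tolerance = 1e-6)
  expect_lt(abs(fit$dispersion - 1), 0.15)
  # intercept-only model fits the sample mean
  d0 <- structure(list(x = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                       y = y, dates = design$dates, blocks = list(),
                       has_h = FALSE), class = "heat_design")
  f0 <- fit_quasipoisson(d0)
  expect_equal(unname(f0$fitted), rep(mean(y), n), tolerance = 1e-8)
})

test_that("Pearson residuals follow the printed formula and square-sum to
           the residual degrees of freedom", {
  fake <- structure(list(fitted = 8, dispersion = 2, y = 10,
                         design = list(has_h = FALSE)), class = "qp_fit")
  expect_equal(pearson_residuals(fake), 0.5)
  expect_equal(pearson_residuals(fake, counts = 8), 0)
  inp <- make_design_inputs(3)
  fit <- fit_quasipoisson(build_design(inp$health, inp$covs))
  r <- pearson_residuals(fit)
  expect_equal(sum(r^2), fit$n - fit$p, tolerance = 1e-8)
  expect_lt(abs(mean(r)), 0.05)
})

test_that("QAIC arithmetic and noise-column penalty behave as expected", {
  f1 <- structure(list(deviance = 100, dispersion = 2, p = 10), class = "qp_fit")
  f2 <- structure(list(deviance = 100, dispersion = 2, p = 12), class = "qp_fit")
  expect_equal(qaic(f2, phi = 2) - qaic(f1, phi = 2), 4)
  f3 <- structure(list(deviance = 100, dispersion = 1, p = 10), class = "qp_fit")
  expect_equal(qaic(f3), 100 + 20)
  # adding a pure-noise column raises QAIC in expectation
  set.seed(33)
  diffs <- replicate(20, {
    n <- 300
    x <- cbind(`(Intercept)` = rep(1, n))
    y <- rpois(n, 20)
    d1 <- structure(list(x = x, y = y, dates = as.Date("2000-05-01") + 1:n,
                         blocks = list(), has_h = FALSE), class = "heat_design")
    d2 <- d1; d2$x <- cbind(x, noise = rnorm(n))
    qaic(fit_quasipoisson(d2)) - qaic(fit_quasipoisson(d1))
  })
  expect_gt(mean(diffs), 0)
})

test_that("risk estimates exponentiate the H coefficient with Wald limits", {
  set.seed(34)
  n <- 2000
  h <- rbinom(n, 1, 0.1)
  x <- cbind(`(Intercept)` = 1, H = h)
  y <- rpois(n, exp(3 + log(1.2) * h))
  design <- structure(list(x = x, y = y, dates = as.Date("2000-05-01") + 1:n,
                           blocks = list(), has_h = TRUE),
                      class = "heat_design")
  fit <- fit_quasipoisson(design)
  re <- risk_estimate(fit)
  expect_equal(re$rr, exp(re$beta_hat))
  expect_equal(re$ci_low, exp(re$beta_hat - 1.96 * re$se))
  expect_true(re$ci_low <= re$rr && re$rr <= re$ci_high)
  expect_lt(abs(re$rr - 1.2), 0.1)
  d0 <- design; d0$has_h <- FALSE
  f0 <- fit; f0$design <- d0
  expect_error(risk_estimate(f0), "no exposure")
})

test_that("adding the exposure column never increases the deviance and
           residuals are uncorrelated with design columns", {
  inp <- make_design_inputs(3, seed = 35)
  d0 <- build_design(inp$health, inp$covs)
  f0 <- fit_quasipoisson(d0)
  set.seed(35)
  h <- rbinom(nrow(d0$x), 1, 0.05)
  f1 <- fit_quasipoisson(heatlogic:::design_with_h(d0, h))
  expect_lte(f1$deviance, f0$deviance + 1e-8)
  r <- pearson_residuals(f0)
  cors <- apply(d0$x[, -1], 2, function(col)
    if (sd(col) > 0) abs(cor(r, col)) else 0)
  expect_lt(max(cors), 0.05)
})
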