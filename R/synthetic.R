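# Synthetic meteorology and health-count generator. Emulates a 20-year
# airport weather record (full calendar years, so percentile thresholds can
# use the whole study period) and overdispersed daily ED visit counts with
# seasonal, day-of-week, holiday and year structure plus a multiplicative
# extreme-heat effect on scenario-defined days.

#' Synthetic weather generator configuration
#'
#' Daily mean temperature follows a sinusoidal annual cycle peaking in
#' mid-July plus an AR(1) anomaly, so exceedances of high percentiles
#' cluster in multi-day runs; hours add a diurnal sinusoid (minimum near
#' 3 am) and noise; dew point tracks the dry bulb minus a slowly varying
#' positive offset. Defaults are calibrated so that warm-season lag-0
#' exceedances of the 98th percentile of daily minimum apparent
#' temperature, their 2-day runs, and ended 2-day runs number roughly
#' 146, 73 and 29 days per 20 seasons, matching the exposure frequencies
#' the estimation procedure is intended to face.
#'
#' @param n_years Number of calendar years (default 20).
#' @param start_year First year (default 1993).
#' @param base_temp Annual mean of daily mean dry-bulb temperature, degC.
#' @param seasonal_amplitude Amplitude of the annual cycle, degC.
#' @param peak_doy Day of year of the seasonal peak (default 196, mid-July).
#' @param rho Lag-1 autocorrelation of the daily anomaly, in [0, 1).
#' @param innovation_sd Innovation SD of the daily anomaly, degC.
#' @param diurnal_amplitude Half-range of the within-day cycle, degC.
#' @param hourly_noise_sd SD of iid hourly noise, degC.
#' @param dewpoint_gap_mean,dewpoint_gap_sd,dewpoint_gap_rho Mean, SD and
#'   lag-1 autocorrelation of the (positive) dry-bulb minus dew-point
#'   daily offset, degC.
#' @param seed Integer seed.
#' @return A `weather_gen_config` list.
#' @export
weather_gen_config <- function(n_years = 20L, start_year = 1993L,
                               base_temp = 17, seasonal_amplitude = 9.5,
                               peak_doy = 196, rho = 0.75,
                               innovation_sd = 1.6,
                               diurnal_amplitude = 5,
                               hourly_noise_sd = 0.3,
                               dewpoint_gap_mean = 4,
                               dewpoint_gap_sd = 1.5,
                               dewpoint_gap_rho = 0.8,
                               seed = 1L) {
  if (rho < 0 || rho >= 1) stop_invalid("rho must be in [0, 1)")
  if (innovation_sd <= 0 || hourly_noise_sd <= 0 || dewpoint_gap_sd <= 0)
    stop_invalid("all SDs must be positive")
  structure(as.list(environment()), class = "weather_gen_config")
}

ar1_series <- function(n, rho, sd_innov) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd_innov / sqrt(1 - rho^2))
  eps <- stats::rnorm(n - 1, 0, sd_innov)
  for (t in 2:n) x[t] <- rho * x[t - 1] + eps[t - 1]
  x
}

#' Simulate an hourly weather record
#'
#' @param config A [weather_gen_config()].
#' @return An [hourly_weather()] data frame covering `n_years` full
#'   calendar years at hourly resolution, with attribute `daily_anomaly`
#'   (the AR(1) daily series, for diagnostics).
#' @export
simulate_hourly_weather <- function(config) {
  stopifnot(inherits(config, "weather_gen_config"))
  with_seed(config$seed, {
    d0 <- as.Date(sprintf("%d-01-01", config$start_year))
    d1 <- as.Date(sprintf("%d-12-31", config$start_year + config$n_years - 1L))
    dates <- seq(d0, d1, by = "day")
    nd <- length(dates)
    doy <- as.integer(format(dates, "%j"))
    seasonal <- config$base_temp + config$seasonal_amplitude *
      cos(2 * pi * (doy - config$peak_doy) / 365.25)
    anom <- ar1_series(nd, config$rho, config$innovation_sd)
    daily_mean <- seasonal + anom
    gap <- config$dewpoint_gap_mean +
      ar1_series(nd, config$dewpoint_gap_rho,
                 config$dewpoint_gap_sd * sqrt(1 - config$dewpoint_gap_rho^2))
    gap <- pmax(gap, 0.5)

    hours <- 0:23
    diurnal <- config$diurnal_amplitude * cos(2 * pi * (hours - 15) / 24)
    nh <- nd * 24L
    dry <- rep(daily_mean, each = 24L) + rep(diurnal, nd) +
      stats::rnorm(nh, 0, config$hourly_noise_sd)
    # dew point is flatter over the day than the dry bulb
    dew <- rep(daily_mean - gap, each = 24L) + 0.2 * rep(diurnal, nd) +
      stats::rnorm(nh, 0, config$hourly_noise_sd)
    dew <- pmin(dew, dry)
    ts <- as.POSIXct(paste0(rep(as.character(dates), each = 24L),
                            sprintf(" %02d:00:00", rep(hours, nd))), tz = "UTC")
    out <- hourly_weather(ts, dry, dew)
    attr(out, "daily_anomaly") <- anom
    out
  })
}

#' True exposure series for a simulation scenario
#'
#' With X1, X2, X3 the lag-0, lag-1 and lag-2 exceedance indicators:
#' E1 (same-day) H = X1; E2 (sustained 2-day) H = X1 AND X2; E3
#' (sustained 2-day, lagged only) H = NOT X1 AND X2 AND X3.
#'
#' @param indicators An `exposure_indicators` data frame (from
#'   [lag_matrix()]) with at least columns lag0..lag2.
#' @param scenario `"E1"`, `"E2"` or `"E3"`.
#' @return Data frame `date`, `h`.
#' @export
scenario_exposure <- function(indicators, scenario = c("E1", "E2", "E3")) {
  scenario <- match.arg(scenario)
  tree <- scenario_tree(scenario)
  x <- as.matrix(indicators[, c("lag0", "lag1", "lag2")])
  data.frame(date = indicators$date, h = evaluate_tree(tree, x))
}

#' @rdname scenario_exposure
#' @return `scenario_tree`: the scenario's `logic_tree` over predictors
#'   (lag0, lag1, lag2) = (1, 2, 3).
#' @export
scenario_tree <- function(scenario = c("E1", "E2", "E3")) {
  scenario <- match.arg(scenario)
  switch(scenario,
         E1 = logic_leaf(1L),
         E2 = logic_node("and", logic_leaf(1L), logic_leaf(2L)),
         E3 = logic_node("and",
                         logic_node("and", logic_leaf(1L, TRUE), logic_leaf(2L)),
                         logic_leaf(3L)))
}

#' Outcome count profiles for simulation
#'
#' Baseline daily means mirror large-, medium- and low-count warm-season
#' ED outcomes (circulatory ~623/day, renal ~139/day, heat illness
#' ~2.5/day). Overdispersion, seasonal amplitude, day-of-week, holiday and
#' year-trend effects are fixed package choices on the log scale.
#'
#' @param name `"CIRC"`, `"RENAL"` or `"HEAT"`.
#' @return A `count_profile` list.
#' @export
count_profile <- function(name = c("CIRC", "RENAL", "HEAT")) {
  name <- match.arg(name)
  p <- switch(name,
    CIRC  = list(baseline_mean = 623, phi = 2.0, seasonal_amplitude = 0.05),
    RENAL = list(baseline_mean = 139, phi = 1.5, seasonal_amplitude = 0.08),
    HEAT  = list(baseline_mean = 2.5, phi = 1.2, seasonal_amplitude = 0.80))
  p$name <- name
  p$dow_effects <- c(Sun = 0, Mon = 0.08, Tue = 0.03, Wed = 0.02,
                     Thu = 0.02, Fri = 0.03, Sat = -0.03)
  p$holiday_effect <- -0.10
  p$year_slope <- 0.01
  structure(p, class = "count_profile")
}

# federal (Memorial Day, July 4, Labor Day) and state (Juneteenth) holiday
# indicator columns for synthetic warm-season dates
synthetic_holidays <- function(dates) {
  yr <- as.integer(format(dates, "%Y"))
  mo <- as.integer(format(dates, "%m"))
  dy <- as.integer(format(dates, "%d"))
  wd <- dow_label(dates)
  memorial <- mo == 5L & wd == "Mon" & dy >= 25L
  labor <- mo == 9L & wd == "Mon" & dy <= 7L
  july4 <- mo == 7L & dy == 4L
  juneteenth <- mo == 6L & dy == 19L
  data.frame(holiday_fed = as.integer(memorial | labor | july4),
             holiday_state = as.integer(juneteenth))
}

# log baseline mean per day, calibrated so the average mean over the given
# dates equals profile$baseline_mean
baseline_log_mean <- function(dates, profile) {
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  dow <- dow_label(dates)
  hol <- synthetic_holidays(dates)
  u <- profile$seasonal_amplitude * cos(2 * pi * (doy - 200) / 365.25) +
    profile$dow_effects[dow] +
    profile$year_slope * (yr - mean(range(yr))) +
    profile$holiday_effect * (hol$holiday_fed > 0 | hol$holiday_state > 0)
  u <- as.numeric(u)
  u + log(profile$baseline_mean) - log(mean(exp(u)))
}

#' Simulate daily counts from a mean model and exposure
#'
#' Counts are negative binomial with mean mu * exp(log_rr * H) and
#' variance phi times the mean (size = mean / (phi - 1)); phi = 1 gives
#' pure Poisson draws.
#'
#' @param mu Baseline daily means (exposure excluded).
#' @param h Binary exposure series (0/1), same length.
#' @param log_rr Log relative risk applied on exposed days.
#' @param phi Dispersion (variance / mean), >= 1.
#' @param seed Integer seed.
#' @return Integer counts.
#' @export
simulate_counts <- function(mu, h, log_rr, phi, seed = NULL) {
  if (any(mu <= 0)) stop_invalid("mean model must be positive")
  if (phi < 1) stop_invalid("dispersion must satisfy variance >= mean (phi >= 1)")
  if (length(h) != length(mu)) stop_invalid("h misaligned with mu")
  m <- mu * exp(log_rr * (h > 0))
  with_seed(seed, {
    if (phi == 1) stats::rpois(length(m), m)
    else stats::rnbinom(length(m), mu = m, size = m / (phi - 1))
  })
}

#' Simulate a complete analysis-ready dataset
#'
#' Generates (or reuses) synthetic hourly weather, derives the truth
#' metric's indicators and threshold, evaluates the scenario exposure, and
#' simulates warm-season daily counts with the planted relative risk.
#'
#' @param scenario `"E1"`, `"E2"` or `"E3"`.
#' @param rr_true True relative risk (> 0), e.g. 1.01 or 1.05.
#' @param profile A [count_profile()] (or its name).
#' @param weather_config A [weather_gen_config()].
#' @param truth_percentile Percentile of the truth metric threshold
#'   (default 98; the truth metric is daily minimum apparent temperature).
#' @param seed Integer seed for the count draw.
#' @param weather Optional pre-simulated [hourly_weather()] to reuse
#'   across replicates.
#' @return List of class `sim_dataset`: `hourly`, `health` (warm-season
#'   `date`, `count`, holiday columns), `truth` (scenario, rr, tree, H
#'   series, threshold, metric) and `daily_atmn`.
#' @export
simulate_dataset <- function(scenario = "E1", rr_true = 1.05,
                             profile = count_profile("CIRC"),
                             weather_config = weather_gen_config(),
                             truth_percentile = 98, seed = 1L,
                             weather = NULL) {
  if (is.character(profile)) profile <- count_profile(profile)
  if (rr_true <= 0) stop_invalid("rr_true must be positive")
  if (is.null(weather)) weather <- simulate_hourly_weather(weather_config)
  metric <- heat_metric_spec("AT", "MN")
  daily <- daily_metric(weather, metric)
  thr <- percentile_threshold(daily, truth_percentile)
  ind <- lag_matrix(extreme_indicator(daily, thr), max_lag = 3L)
  h_all <- scenario_exposure(ind, scenario)
  warm <- is_warm_season(h_all$date)
  dates <- h_all$date[warm]
  h <- h_all$h[warm]
  h[is.na(h)] <- 0L  # first days of the record with unavailable lags
  mu <- exp(baseline_log_mean(dates, profile))
  counts <- simulate_counts(mu, h, log(rr_true), profile$phi, seed = seed)
  health <- cbind(data.frame(date = dates, count = counts),
                  synthetic_holidays(dates))
  structure(list(hourly = weather, health = health,
                 truth = list(scenario = scenario, rr_true = rr_true,
                              tree = scenario_tree(scenario),
                              h = data.frame(date = dates, h = h),
                              threshold = thr, metric = metric,
                              profile = profile$name, phi = profile$phi,
                              mu = mu),
                 daily_atmn = daily, indicators = ind),
            class = "sim_dataset")
}
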