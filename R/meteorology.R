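#' Saturation water vapor pressure at the dew point
#'
#' Converts dew-point temperature to water vapor pressure using the
#' Magnus-Tetens approximation over water (WMO constants), returned in kPa.
#' The actual vapor pressure of an air parcel equals the saturation vapor
#' pressure evaluated at its dew point, which is what the apparent
#' temperature formula needs.
#'
#' @param dew_point Dew-point temperature in degrees Celsius. Must be finite
#'   and physically plausible (-40 to 45).
#' @return Water vapor pressure in kPa, strictly increasing in `dew_point`.
#' @examples
#' water_vapor_pressure(20) > water_vapor_pressure(10)
#' @export
water_vapor_pressure <- function(dew_point) {
  if (!is.numeric(dew_point) || any(!is.finite(dew_point)))
    stop_invalid("dew_point must be finite numeric")
  if (any(dew_point < -40 | dew_point > 45))
    stop_invalid("dew_point outside the plausible range -40..45 degC")
  0.6112 * exp(17.62 * dew_point / (243.12 + dew_point))
}

#' Apparent temperature
#'
#' Heat-index-like measure combining air temperature and humidity:
#' AT = -1.3 + 0.92 T + 2.2 e, with T the dry-bulb temperature in degC and
#' e the water vapor pressure in kPa.
#'
#' @param temp Dry-bulb temperature, degC.
#' @param e Water vapor pressure, kPa.
#' @return Apparent temperature, degC.
#' @examples
#' apparent_temperature(30, 3)  # 32.9
#' @export
apparent_temperature <- function(temp, e) {
  if (any(!is.finite(temp)) || any(!is.finite(e)))
    stop_invalid("inputs to apparent_temperature must be finite")
  -1.3 + 0.92 * temp + 2.2 * e
}

#' Hourly weather container
#'
#' Validates an hourly weather series and computes apparent temperature
#' when it is not supplied.
#'
#' @param timestamp POSIXct timestamps, strictly increasing (local time).
#' @param dry_bulb Dry-bulb temperature, degC.
#' @param dew_point Dew-point temperature, degC.
#' @param apparent Optional apparent temperature, degC; computed from
#'   `dry_bulb` and `dew_point` when `NULL`.
#' @return A `data.frame` of class `hourly_weather` with columns
#'   `timestamp`, `dry_bulb`, `dew_point`, `apparent`.
#' @export
hourly_weather <- function(timestamp, dry_bulb, dew_point, apparent = NULL) {
  if (!inherits(timestamp, "POSIXct")) timestamp <- as.POSIXct(timestamp, tz = "UTC")
  if (is.unsorted(timestamp, strictly = TRUE))
    stop_invalid("timestamps must be strictly increasing")
  n <- length(timestamp)
  stopifnot(length(dry_bulb) == n, length(dew_point) == n)
  ok <- is.finite(dry_bulb) & is.finite(dew_point)
  if (any(dew_point[ok] > dry_bulb[ok] + 0.5))
    warning("dew_point exceeds dry_bulb beyond measurement tolerance on ",
            sum(dew_point[ok] > dry_bulb[ok] + 0.5), " hours")
  gaps <- diff(as.numeric(timestamp)) > 3600
  if (any(gaps)) attr(timestamp, "n_gaps") <- sum(gaps)
  if (is.null(apparent)) {
    apparent <- rep(NA_real_, n)
    apparent[ok] <- apparent_temperature(dry_bulb[ok],
                                         water_vapor_pressure(dew_point[ok]))
  }
  out <- data.frame(timestamp = timestamp, dry_bulb = dry_bulb,
                    dew_point = dew_point, apparent = apparent)
  class(out) <- c("hourly_weather", "data.frame")
  out
}

#' Specify a daily heat metric
#'
#' The six metrics are the daily maximum (MX), minimum (MN) and average
#' (Avg) of either dry-bulb temperature (T) or apparent temperature (AT).
#'
#' @param variable `"T"` or `"AT"`.
#' @param statistic `"MX"`, `"MN"` or `"Avg"`.
#' @return A `heat_metric_spec` object.
#' @export
heat_metric_spec <- function(variable = c("T", "AT"),
                             statistic = c("MX", "MN", "Avg")) {
  variable <- match.arg(variable)
  statistic <- match.arg(statistic)
  structure(list(variable = variable, statistic = statistic),
            class = "heat_metric_spec")
}

#' @export
format.heat_metric_spec <- function(x, ...) paste0(x$variable, x$statistic)

#' @export
print.heat_metric_spec <- function(x, ...) {
  cat("heat metric:", format(x), "\n"); invisible(x)
}

#' All six heat metric specifications
#' @return List of the six `heat_metric_spec` combinations.
#' @export
all_heat_metrics <- function() {
  out <- list()
  for (v in c("T", "AT")) for (s in c("MX", "MN", "Avg"))
    out[[paste0(v, s)]] <- heat_metric_spec(v, s)
  out
}

#' Daily heat metric from hourly weather
#'
#' Aggregates the chosen variable to one value per calendar day. Days with
#' fewer than `min_hours` contributing observations are set to missing.
#'
#' @param hourly An `hourly_weather` object (or compatible data frame).
#' @param spec A `heat_metric_spec`.
#' @param min_hours Minimum hourly observations required for a daily value
#'   (default 18 of 24).
#' @return A `data.frame` with columns `date`, `value`, `n_hours`, of class
#'   `daily_metric`; the metric spec is attached as attribute `metric`.
#' @export
daily_metric <- function(hourly, spec, min_hours = 18L) {
  if (!inherits(spec, "heat_metric_spec")) stop_invalid("spec must be a heat_metric_spec")
  if (min_hours < 1 || min_hours > 24) stop_invalid("min_hours must be in 1..24")
  if (nrow(hourly) == 0L) {
    out <- data.frame(date = as.Date(character()), value = numeric(),
                      n_hours = integer())
    class(out) <- c("daily_metric", "data.frame")
    attr(out, "metric") <- spec
    return(out)
  }
  v <- if (spec$variable == "T") hourly$dry_bulb else hourly$apparent
  date <- as.Date(format(hourly$timestamp, "%Y-%m-%d"))
  keep <- is.finite(v)
  f <- switch(spec$statistic, MX = max, MN = min, Avg = mean)
  dates <- sort(unique(date))
  n_hours <- as.integer(tapply(keep, date, sum)[as.character(dates)])
  val <- rep(NA_real_, length(dates))
  agg <- tapply(v[keep], date[keep], f)
  idx <- match(names(agg), as.character(dates))
  val[idx] <- as.numeric(agg)
  val[n_hours < min_hours] <- NA_real_
  out <- data.frame(date = dates, value = val, n_hours = n_hours)
  class(out) <- c("daily_metric", "data.frame")
  attr(out, "metric") <- spec
  out
}

#' Daily maximum dew point
#'
#' Same-day maximum dew-point temperature, used as the humidity covariate
#' when dry-bulb temperature is the exposure of interest.
#'
#' @inheritParams daily_metric
#' @return A `daily_metric`-style data frame.
#' @export
daily_max_dewpoint <- function(hourly, min_hours = 18L) {
  h2 <- hourly
  h2$apparent <- h2$dew_point  # reuse the aggregator on the AT slot
  out <- daily_metric(h2, heat_metric_spec("AT", "MX"), min_hours)
  attr(out, "metric") <- list(variable = "DPT", statistic = "MX")
  out
}

#' Percentile threshold for a daily heat metric
#'
#' Computes the stated quantile of the daily series restricted to
#' `basis_dates`, by default all available days of the record (matching a
#' threshold defined over the full multi-year study period). Linear
#' interpolation between order statistics (quantile type 7) is used so
#' thresholds are bit-reproducible.
#'
#' @param daily A `daily_metric` data frame.
#' @param percentile One of 95, 98, 99.
#' @param basis_dates Optional `Date` vector restricting the basis series;
#'   default uses every non-missing day.
#' @return A `threshold_spec` list: `percentile`, `value` (degC),
#'   `n_basis`.
#' @export
percentile_threshold <- function(daily, percentile, basis_dates = NULL) {
  if (!percentile %in% c(95, 98, 99))
    stop_invalid("percentile must be one of 95, 98, 99")
  x <- daily$value
  if (!is.null(basis_dates)) x <- x[daily$date %in% basis_dates]
  x <- x[is.finite(x)]
  if (length(x) < 100L)
    stop_invalid("need at least 100 non-missing basis values to estimate a ",
                 percentile, "th percentile")
  structure(list(percentile = percentile,
                 value = unname(stats::quantile(x, percentile / 100, type = 7)),
                 n_basis = length(x)),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("P%d threshold: %.3f degC (basis n = %d)\n",
              x$percentile, x$value, x$n_basis))
  invisible(x)
}

#' Binary extreme-heat indicator
#'
#' 1 when the daily metric strictly exceeds the threshold value, 0
#' otherwise; ties count as non-extreme. Missing daily values propagate.
#'
#' @param daily A `daily_metric` data frame.
#' @param threshold A `threshold_spec`.
#' @return Data frame `date`, `x` with `x` in \{0, 1, NA\}.
#' @export
extreme_indicator <- function(daily, threshold) {
  x <- as.integer(daily$value > threshold$value)
  data.frame(date = daily$date, x = x)
}

#' Lagged indicator matrix
#'
#' Column for lag `l` on date `t` holds the indicator observed on date
#' `t - l`. Leading dates whose lags precede the record are missing.
#'
#' @param indicator Data frame `date`, `x` from [extreme_indicator()].
#' @param max_lag Largest lag (default 3, giving columns lag0..lag3).
#' @return Data frame of class `exposure_indicators` with columns `date`,
#'   `lag0`, ..., `lag<max_lag>`.
#' @export
lag_matrix <- function(indicator, max_lag = 3L) {
  if (max_lag < 0) stop_invalid("max_lag must be >= 0")
  n <- nrow(indicator)
  # require contiguous daily dates for shift semantics
  if (n > 1 && any(diff(as.integer(indicator$date)) != 1L))
    stop_invalid("indicator series must be daily and contiguous")
  out <- data.frame(date = indicator$date)
  for (l in 0:max_lag) {
    col <- rep(NA_integer_, n)
    if (n > l) col[(l + 1):n] <- indicator$x[1:(n - l)]
    out[[paste0("lag", l)]] <- col
  }
  class(out) <- c("exposure_indicators", "data.frame")
  out
}

#' Truncate a daily metric at the extreme threshold
#'
#' Sets any value above the threshold to the threshold value, so the
#' continuous temperature covariate carries no information beyond the
#' extreme cutoff (the binary exposure term absorbs it).
#'
#' @inheritParams extreme_indicator
#' @return The `daily_metric` with values capped at `threshold$value`.
#' @export
truncate_at_threshold <- function(daily, threshold) {
  daily$value <- pmin(daily$value, threshold$value)
  daily
}

#' Mean of lags 1-3 of a daily series
#'
#' Value at day t is the mean of the values at t-1, t-2, t-3; missing when
#' any of the three lags is missing or unavailable.
#'
#' @param daily A `daily_metric` data frame (contiguous daily dates).
#' @return Data frame `date`, `value`.
#' @export
lag123_mean <- function(daily) {
  n <- nrow(daily)
  if (n < 4L) stop_invalid("need at least 4 days of data")
  if (any(diff(as.integer(daily$date)) != 1L))
    stop_invalid("daily series must be contiguous")
  v <- daily$value
  out <- rep(NA_real_, n)
  out[4:n] <- (v[3:(n - 1)] + v[2:(n - 2)] + v[1:(n - 3)]) / 3
  data.frame(date = daily$date, value = out)
}

#' Continuous temperature covariates for the time-series model
#'
#' Builds the same-day metric (optionally truncated at the extreme
#' threshold), the lag 1-3 mean of the (optionally truncated) metric, and
#' the same-day maximum dew point.
#'
#' @param daily A `daily_metric` for the exposure metric being scanned.
#' @param dpt Optional `daily_metric` of daily maximum dew point (from
#'   [daily_max_dewpoint()]); omitted when the exposure variable is
#'   apparent temperature.
#' @param threshold A `threshold_spec`, required when `truncate = TRUE`.
#' @param truncate Cap the continuous metric at the threshold (default
#'   TRUE, the primary analysis).
#' @return Data frame `date`, `temp`, `temp_bar`, `dpt` (dpt may be NA
#'   column when not supplied), with attribute `truncated`.
#' @export
continuous_temp_covariates <- function(daily, dpt = NULL, threshold = NULL,
                                       truncate = TRUE) {
  base <- daily
  if (truncate) {
    if (is.null(threshold)) stop_invalid("truncation requires a threshold")
    base <- truncate_at_threshold(daily, threshold)
  }
  tbar <- lag123_mean(base)
  out <- data.frame(date = base$date, temp = base$value,
                    temp_bar = tbar$value)
  out$dpt <- if (is.null(dpt)) NA_real_ else dpt$value[match(out$date, dpt$date)]
  attr(out, "truncated") <- truncate
  out
}
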