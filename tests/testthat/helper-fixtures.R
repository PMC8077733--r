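# Fixtures built in code: a small synthetic hourly record and planted
# tree-recovery instances shared across test files.

# one day's hourly record (24 hours) at the given date with values v
make_hourly_day <- function(date, dry, dew = dry - 4) {
  ts <- as.POSIXct(paste(date, sprintf("%02d:00:00", 0:23)), tz = "UTC")
  hourly_weather(ts, dry, dew)
}

# a short multi-day hourly record with a sinusoidal diurnal cycle
make_hourly_span <- function(start = as.Date("2000-05-01"), n_days = 30,
                             daily_mean = NULL, gap = 4) {
  if (is.null(daily_mean)) daily_mean <- 20 + sin(seq_len(n_days) / 3)
  dates <- start + seq_len(n_days) - 1L
  ts <- as.POSIXct(paste(rep(as.character(dates), each = 24),
                         sprintf("%02d:00:00", rep(0:23, n_days))), tz = "UTC")
  dry <- rep(daily_mean, each = 24) + 5 * cos(2 * pi * (rep(0:23, n_days) - 15) / 24)
  hourly_weather(ts, dry, dry - gap)
}

# planted-signal instance: binary indicator matrix with serial clustering
# (built through lag_matrix) and residuals elevated under a target tree
make_planted_instance <- function(n_days = 1500, k = 4, tree,
                                  effect = 1, noise_sd = 1, seed = 1,
                                  p_exceed = 0.08, rho = 0.6) {
  set.seed(seed)
  z <- numeric(n_days + k)
  z[1] <- rnorm(1)
  for (t in 2:length(z)) z[t] <- rho * z[t - 1] + rnorm(1, 0, sqrt(1 - rho^2))
  ind <- data.frame(date = as.Date("2000-01-01") + seq_along(z) - 1L,
                    x = as.integer(z > qnorm(1 - p_exceed)))
  lm <- lag_matrix(ind, max_lag = k - 1L)
  x <- as.matrix(lm[-seq_len(k - 1L), paste0("lag", 0:(k - 1L))])
  h <- evaluate_tree(tree, x)
  r <- effect * h + rnorm(nrow(x), 0, noise_sd)
  list(x = x, r = r, h = h)
}

# small warm-season count dataset driven by the synthetic generator, sized
# for quick model fits
small_sim <- function(scenario = "E1", rr = 1.05, n_years = 6, seed = 7,
                      profile = count_profile("CIRC")) {
  wc <- weather_gen_config(n_years = n_years, seed = seed)
  simulate_dataset(scenario, rr, profile, weather_config = wc, seed = seed)
}
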