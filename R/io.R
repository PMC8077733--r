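# Delimited-text readers and writers for the standard input/output files.

#' Read an hourly weather file
#'
#' Expects a header `timestamp,dry_bulb_c,dew_point_c[,apparent_c]` with
#' ISO-8601 timestamps; apparent temperature is computed when absent.
#'
#' @param path CSV file path.
#' @return An [hourly_weather()] data frame.
#' @export
read_hourly_weather <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "dry_bulb_c", "dew_point_c")
  if (!all(need %in% names(d)))
    stop_invalid("hourly weather file must have columns ",
                 paste(need, collapse = ", "))
  hourly_weather(as.POSIXct(d$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                           "%Y-%m-%d %H:%M:%S")),
                 d$dry_bulb_c, d$dew_point_c,
                 if ("apparent_c" %in% names(d)) d$apparent_c else NULL)
}

#' Write an hourly weather file
#' @param hourly An [hourly_weather()] data frame.
#' @param path Output CSV path.
#' @export
write_hourly_weather <- function(hourly, path) {
  utils::write.csv(
    data.frame(timestamp = format(hourly$timestamp, "%Y-%m-%dT%H:%M:%S"),
               dry_bulb_c = hourly$dry_bulb,
               dew_point_c = hourly$dew_point,
               apparent_c = hourly$apparent),
    path, row.names = FALSE, quote = FALSE)
}

#' Read a daily health count file
#'
#' Expects `date,count` plus optional `holiday_*` and `hosp_*` indicator
#' columns.
#'
#' @param path CSV file path.
#' @return Data frame with `date` as `Date`.
#' @export
read_daily_counts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "count") %in% names(d)))
    stop_invalid("daily counts file must have columns date, count")
  d$date <- as.Date(d$date)
  if (any(d$count < 0, na.rm = TRUE)) stop_invalid("counts must be >= 0")
  d
}

#' Write a daily health count file
#' @param health Data frame with `date`, `count` and optional indicator
#'   columns.
#' @param path Output CSV path.
#' @export
write_daily_counts <- function(health, path) {
  utils::write.csv(health, path, row.names = FALSE, quote = FALSE)
}
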