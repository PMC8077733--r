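# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Keeps exported functions deterministic
# without clobbering the user's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a reproducible child seed from a master seed and a string tag.
# Must stay below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483587L) + 1L
}

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Warm-season membership of dates
#'
#' The analysis window is May 1 through September 30; thresholds may use
#' the full record but model rows are restricted to these dates.
#'
#' @param dates A `Date` vector.
#' @return Logical vector, TRUE for May-September dates.
#' @export
is_warm_season <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  m >= 5L & m <= 9L
}

# locale-independent day-of-week labels (Unix epoch day 0 was a Thursday)
dow_label <- function(dates) {
  c("Thu", "Fri", "Sat", "Sun", "Mon", "Tue", "Wed")[
    as.integer(as.numeric(dates)) %% 7L + 1L]
}

day_of_season <- function(dates) {
  # 1 = May 1 ... 153 = Sep 30; NA outside the warm season
  doy <- as.integer(format(dates, "%j"))
  may1 <- as.integer(format(as.Date(paste0(format(dates, "%Y"), "-05-01")), "%j"))
  out <- doy - may1 + 1L
  out[!is_warm_season(dates)] <- NA_integer_
  out
}
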