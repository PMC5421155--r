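#' Circular day-of-year arithmetic
#'
#' All scheduling in cropgap happens on a fixed 365-day circle with 1-based
#' day-of-year (DOY). Leap days are ignored: simulation years are labels, not
#' calendar years. `wrap_doy()` folds any integer onto 1..365; `gap_days()`
#' measures the forward (clockwise) distance from the end of one crop cycle to
#' the start of the next, so that a cycle occupying `[start, end)` followed
#' immediately by another gives a gap of zero.
#'
#' @param doy Integer vector of (possibly out-of-range) day numbers.
#' @return `wrap_doy()`: integer vector in 1..365.
#' @examples
#' wrap_doy(366)       # 1
#' gap_days(248, 274)  # 26-day turnaround
#' gap_days(360, 10)   # 15, across the year boundary
#' @export
wrap_doy <- function(doy) {
  ((as.integer(doy) - 1L) %% 365L) + 1L
}

#' @rdname wrap_doy
#' @param end_doy DOY at which the preceding cycle ends (first free day).
#' @param next_start_doy DOY at which the following cycle starts.
#' @return `gap_days()`: integer fallow days between the two cycles
#'   (0 means same-day succession).
#' @export
gap_days <- function(end_doy, next_start_doy) {
  check_doy(end_doy, "end_doy")
  check_doy(next_start_doy, "next_start_doy")
  (as.integer(next_start_doy) - as.integer(end_doy)) %% 365L
}

check_doy <- function(doy, what = "doy") {
  if (any(!is.finite(doy)) || any(doy < 1) || any(doy > 365) ||
      any(doy != floor(doy))) {
    stop(sprintf("`%s` must be integer day-of-year in 1..365", what),
         call. = FALSE)
  }
  invisible(doy)
}

#' Convert a day-month string to day-of-year
#'
#' Fixture tables carry human-readable dates like "15-Jun"; these are mapped
#' onto the non-leap 365-day calendar (15-Jun = 166, 1-Oct = 274).
#'
#' @param x Character vector like `"6-Feb"` (day-abbreviated month).
#' @return Integer DOY in 1..365.
#' @export
doy_from_date <- function(x) {
  month_len <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  cum <- c(0L, cumsum(month_len)[-12])
  parts <- strsplit(as.character(x), "-", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L) stop("expected 'day-Mon' date strings", call. = FALSE)
    m <- match(tolower(substr(p[2], 1, 3)), tolower(month.abb))
    if (is.na(m)) stop("unknown month in date string: ", p[2], call. = FALSE)
    d <- as.integer(p[1])
    if (is.na(d) || d < 1L || d > month_len[m]) {
      stop("invalid day of month in date string", call. = FALSE)
    }
    cum[m] + d
  }, integer(1))
}

# Cycle length under the half-open [start, end) convention: a cycle sown on
# DOY 274 maturing on DOY 37 occupies 128 days. With this convention the
# durations and turnaround gaps of a feasible annual sequence always sum to
# exactly 365.
cycle_duration <- function(start_doy, end_doy) {
  gap_days(start_doy, end_doy)
}

cycle_end <- function(start_doy, duration) {
  check_doy(start_doy, "start_doy")
  if (any(duration < 1)) stop("`duration` must be >= 1 day", call. = FALSE)
  wrap_doy(as.integer(start_doy) + as.integer(duration))
}

# Report-style rounding used throughout the printed tables: round half away
# from zero (so 18.15 -> 18.2 and 239.76 -> 240), unlike base round()'s
# round-half-even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # guard digit: 18.15 * 10 is 181.4999... in binary; snap before flooring
  sign(x) * floor(round(abs(x) * p, 8) + 0.5) / p
}
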