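#' Experiment calendar utilities
#'
#' Dates in a multi-year pot experiment are stored as (year index, day of
#' year) pairs so that periods wrapping around the new year (e.g. autumn of
#' year 1 to early spring of year 2) stay representable. For ordering and
#' interval arithmetic, dates are mapped to an absolute day index on a
#' fixed 365-day year; leap days are irrelevant at the precision of the
#' analysis and a fixed-length year keeps the mapping invertible.
#'
#' @param year integer year index (1-based).
#' @param doy integer day of year, 1--365.
#' @return `abs_day()` returns an integer day index; `default_periods()`
#'   returns a data.frame with one row per production period.
#' @examples
#' abs_day(2, 1) - abs_day(1, 365)  # consecutive days across the year wrap
#' @export
abs_day <- function(year, doy) {
  stopifnot(all(doy >= 1), all(doy <= 365), all(year >= 1))
  (as.integer(year) - 1L) * 365L + as.integer(doy)
}

#' @rdname abs_day
#' @details The default calendar has six biomass production periods bounded
#'   by cutting dates: spring year 1 (DOY 113--143), early summer year 1
#'   (144--190), late summer year 1 (191--224), autumn year 1 (225--280),
#'   autumn year 1 to early spring year 2 (281--101) and spring year 2
#'   (102--161).
#' @export
default_periods <- function() {
  p <- data.frame(
    period     = c("113-143", "144-190", "191-224", "225-280",
                   "281-101", "102-161"),
    year_start = c(1L, 1L, 1L, 1L, 1L, 2L),
    doy_start  = c(113L, 144L, 191L, 225L, 281L, 102L),
    year_end   = c(1L, 1L, 1L, 1L, 2L, 2L),
    doy_end    = c(143L, 190L, 224L, 280L, 101L, 161L),
    stringsAsFactors = FALSE
  )
  p$day_start <- abs_day(p$year_start, p$doy_start)
  p$day_end   <- abs_day(p$year_end, p$doy_end)
  stopifnot(all(p$day_end > p$day_start))
  p
}

# locate the period containing an absolute day; NA if outside all periods
period_of_day <- function(day, periods) {
  idx <- rep(NA_integer_, length(day))
  for (i in seq_len(nrow(periods))) {
    hit <- day >= periods$day_start[i] & day <= periods$day_end[i]
    idx[hit] <- i
  }
  periods$period[idx]
}
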