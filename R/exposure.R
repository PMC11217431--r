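
#' Lag window specification
#'
#' Defines the lag window over which daily temperature exposures act on the
#' risk of death: lags `l0` (usually 0, the day of death) through `L` days
#' before the event. The default window of 0--2 days reflects the acute,
#' short-delay nature of temperature effects on neonatal mortality.
#'
#' @param l0 minimum lag in days (non-negative integer).
#' @param L maximum lag in days, `L >= l0`.
#' @return An object of class `lag_spec`.
#' @examples
#' lag_spec(0, 2)
#' @export
lag_spec <- function(l0 = 0L, L = 2L) {
  if (!is_wholenumber(l0) || !is_wholenumber(L)) {
    stopf("lag bounds must be integers")
  }
  l0 <- as.integer(round(l0)); L <- as.integer(round(L))
  if (l0 < 0L || l0 > L) stopf("invalid lag window: need 0 <= l0 <= L")
  structure(list(l0 = l0, L = L), class = "lag_spec")
}

n_lags <- function(lag) lag$L - lag$l0 + 1L

#' @export
print.lag_spec <- function(x, ...) {
  cat(sprintf("<lag_spec> lags %d..%d (%d days)\n", x$l0, x$L, n_lags(x)))
  invisible(x)
}

#' Daily temperature series for one location and scenario
#'
#' Light-weight constructor/validator for a complete daily mean-temperature
#' series at one location under one scenario (factual or counterfactual) of
#' one temperature dataset. Enforces a contiguous, strictly increasing daily
#' calendar with no missing values.
#'
#' @param location_id location (grid cell) identifier.
#' @param dates vector of `Date`s, one per day.
#' @param tmean daily mean temperature in degrees Celsius.
#' @param scenario `"factual"` or `"counterfactual"`.
#' @param dataset_id name of the temperature product the series comes from.
#' @return A `data.frame` of class `scenario_series` with columns
#'   `location_id`, `dataset_id`, `scenario`, `date`, `tmean`.
#' @export
scenario_series <- function(location_id, dates, tmean,
                            scenario = c("factual", "counterfactual"),
                            dataset_id = "synthetic") {
  scenario <- match.arg(scenario)
  dates <- as.Date(dates)
  if (length(dates) != length(tmean)) stopf("dates and tmean lengths differ")
  if (anyNA(dates) || anyNA(tmean)) stopf("scenario series contains missing days or values")
  dd <- diff(as.integer(dates))
  if (length(dd) && any(dd != 1L)) stopf("scenario series calendar is not contiguous daily")
  structure(
    data.frame(location_id = as.character(location_id),
               dataset_id = as.character(dataset_id),
               scenario = scenario, date = dates, tmean = as.numeric(tmean),
               stringsAsFactors = FALSE),
    class = c("scenario_series", "data.frame"))
}

#' Fit a location-specific temperature percentile map
#'
#' Converts absolute temperatures to location-specific percentiles so that
#' populations living in different climate zones can be pooled on a common
#' exposure scale. The empirical map uses the Hazen plotting position,
#' `percentile(x) = 100 * (rank(x) - 0.5) / n`, with mid-ranks for ties;
#' values between observed temperatures are linearly interpolated and values
#' outside the observed range are clamped to the extreme Hazen percentiles.
#'
#' The reference sample should be the location's *factual* series over the
#' study period; the counterfactual is then expressed through the same map so
#' that one fitted exposure-response curve applies to both scenarios.
#'
#' @param series a [scenario_series] or a numeric vector of reference
#'   temperatures.
#' @param min_n minimum reference sample size (default one year of days).
#' @return An object of class `percentile_map`.
#' @examples
#' pm <- fit_percentile_map(c(10, 20, 30, 40), min_n = 4)
#' map_percentile(pm, 20) # 37.5
#' @export
fit_percentile_map <- function(series, min_n = 365L) {
  x <- if (inherits(series, "scenario_series") || is.data.frame(series)) {
    series$tmean
  } else {
    as.numeric(series)
  }
  loc <- if (is.data.frame(series)) series$location_id[1] else NA_character_
  if (anyNA(x)) stopf("reference sample contains missing values")
  n <- length(x)
  if (n < min_n) stopf("reference sample too short (n = %d < %d)", n, min_n)
  xs <- sort(x)
  ux <- unique(xs)
  # mid-rank for each unique value: #{< v} + (#{= v} + 1) / 2
  cnt <- tabulate(match(xs, ux))
  below <- cumsum(c(0, cnt[-length(cnt)]))
  midrank <- below + (cnt + 1) / 2
  pct <- 100 * (midrank - 0.5) / n
  structure(list(location_id = loc, n = n, x = ux, pct = pct,
                 convention = "hazen"),
            class = "percentile_map")
}

#' Apply a percentile map
#'
#' @param map a [fit_percentile_map] result.
#' @param x numeric temperatures (degrees Celsius).
#' @return Percentiles in `(0, 100)`; out-of-range inputs are clamped to the
#'   lowest/highest Hazen percentile of the reference sample.
#' @export
map_percentile <- function(map, x) {
  stopifnot(inherits(map, "percentile_map"))
  if (length(map$x) == 1L) return(rep(50, length(x)))
  stats::approx(map$x, map$pct, xout = x, rule = 2, ties = "ordered")$y
}

#' Convert a temperature series to percentiles
#'
#' @param map a [fit_percentile_map] result.
#' @param series a [scenario_series] (any scenario) or numeric vector.
#' @return For a data frame input, the same frame with a `pct` column added;
#'   for a numeric input, a numeric vector of percentiles.
#' @export
map_series <- function(map, series) {
  if (is.data.frame(series)) {
    series$pct <- map_percentile(map, series$tmean)
    series
  } else {
    map_percentile(map, series)
  }
}

#' @export
print.percentile_map <- function(x, ...) {
  cat(sprintf("<percentile_map> location %s, n = %d reference days (%s)\n",
              x$location_id, x$n, x$convention))
  invisible(x)
}

#' Lagged exposure vector for one calendar day
#'
#' Returns the percentile exposures experienced on days `day - l0` through
#' `day - L`, ordered by increasing lag (element 1 is lag `l0`).
#'
#' @param pct_series data frame with columns `date` and `pct` (one location,
#'   one scenario), or a [map_series] result.
#' @param day the case day (a `Date`).
#' @param lag a [lag_spec].
#' @return Numeric vector of length `L - l0 + 1`.
#' @export
lagged_exposure <- function(pct_series, day, lag = lag_spec()) {
  day <- as.Date(day)
  want <- day - seq(lag$l0, lag$L)
  i <- match(as.integer(want), as.integer(pct_series$date))
  if (anyNA(i)) {
    stopf("exposure series does not cover %s",
          paste(format(want[is.na(i)]), collapse = ", "))
  }
  pct_series$pct[i]
}
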