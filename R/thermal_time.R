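#' Daily growing degree days for cotton
#'
#' Computes the daily thermal-time increment from the daily temperature
#' extremes: `(min(tmax, ceiling) + tmin) / 2 - base`, floored at zero.
#' Cotton development is assumed to stop below the base temperature
#' (15.6 degC) and not to accelerate above the upper threshold of maximum
#' temperature (33.9 degC); only the maximum temperature is capped.
#'
#' @param tmax daily maximum air temperature, degC. Vectorized.
#' @param tmin daily minimum air temperature, degC.
#' @param base base temperature, degC (default 15.6).
#' @param ceiling upper threshold applied to `tmax`, degC (default 33.9).
#' @return daily GDD in degC day, same length as `tmax`.
#' @examples
#' daily_gdd(30, 20)   # 9.4
#' daily_gdd(40, 20)   # tmax capped at 33.9 -> 11.35
#' daily_gdd(15, 5)    # mean below base -> 0
#' @export
daily_gdd <- function(tmax, tmin, base = 15.6, ceiling = 33.9) {
  if (length(tmax) != length(tmin)) {
    if (length(tmax) == 1L) tmax <- rep(tmax, length(tmin))
    else if (length(tmin) == 1L) tmin <- rep(tmin, length(tmax))
    else stop("'tmax' and 'tmin' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(tmax)) || any(!is.finite(tmin))) {
    stop("temperatures must be finite", call. = FALSE)
  }
  if (any(tmax < tmin)) {
    bad <- which(tmax < tmin)[1L]
    stop(sprintf("invalid weather: tmax < tmin (first at position %d)", bad),
         call. = FALSE)
  }
  pmax(0, (pmin(tmax, ceiling) + tmin) / 2 - base)
}

#' Accumulate growing degree days from planting
#'
#' Sums [daily_gdd()] from the planting day through `until_date`
#' inclusive (measurements on a sampling date include that day's GDD).
#' The weather table must cover every day of the range with no gaps.
#'
#' @param weather data frame with columns `date` (Date or ISO-8601
#'   string), `tmax_c`, `tmin_c` and optionally `solar_mj_m2`.
#' @param planting_date first day of accumulation (day 1).
#' @param until_date last day of accumulation, inclusive.
#' @inheritParams daily_gdd
#' @return data frame with columns `date`, `daily_gdd`, `cumulative_gdd`,
#'   one row per day from planting through `until_date`.
#' @export
accumulate_gdd <- function(weather, planting_date, until_date,
                           base = 15.6, ceiling = 33.9) {
  planting_date <- as.Date(planting_date)
  until_date <- as.Date(until_date)
  if (until_date < planting_date) {
    stop("'until_date' precedes 'planting_date'", call. = FALSE)
  }
  w <- check_weather(weather)
  wanted <- seq(planting_date, until_date, by = "day")
  idx <- match(wanted, w$date)
  if (anyNA(idx)) {
    missing_day <- wanted[which(is.na(idx))[1L]]
    stop(sprintf("weather gap: no record for %s", format(missing_day)),
         call. = FALSE)
  }
  g <- daily_gdd(w$tmax_c[idx], w$tmin_c[idx], base = base, ceiling = ceiling)
  data.frame(date = wanted, daily_gdd = g, cumulative_gdd = cumsum(g))
}

#' Read a daily weather table
#'
#' Expects a CSV with header `date, tmax_c, tmin_c, solar_mj_m2`
#' (ISO-8601 dates; temperatures in degC; daily total solar radiation in
#' MJ m-2 d-1).
#'
#' @param path CSV file path.
#' @return validated weather data frame with a `Date` column.
#' @export
read_weather_csv <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_weather(w)
}

check_weather <- function(weather) {
  need <- c("date", "tmax_c", "tmin_c")
  miss <- setdiff(need, names(weather))
  if (length(miss)) {
    stop(sprintf("weather table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  weather$date <- as.Date(weather$date)
  if (anyNA(weather$date)) stop("unparseable weather dates", call. = FALSE)
  if (any(weather$tmax_c < weather$tmin_c)) {
    stop("invalid weather: tmax < tmin", call. = FALSE)
  }
  if (!is.null(weather$solar_mj_m2) && any(weather$solar_mj_m2 < 0)) {
    stop("invalid weather: negative solar radiation", call. = FALSE)
  }
  weather
}
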