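#' Fraction of intercepted PAR from ceptometer readings
#'
#' `(PAR_above - PAR_below) / PAR_above`, clamped to the open interval
#' `[eps, 1 - eps]` so the beta likelihood used downstream stays finite
#' at full transmission or full interception. Any consistent PAR unit
#' cancels. A below-canopy reading exceeding the above-canopy one (a
#' physically impossible but observable sensor state) is clamped to
#' `eps` with a warning.
#'
#' @param par_above above-canopy PAR reading (> 0).
#' @param par_below below-canopy PAR reading (>= 0).
#' @param eps open-interval clamp (default 1e-6).
#' @return interception fraction in `(0, 1)`. Vectorized.
#' @export
ipar_fraction <- function(par_above, par_below, eps = 1e-6) {
  if (any(!is.finite(par_above)) || any(!is.finite(par_below))) {
    stop("PAR readings must be finite", call. = FALSE)
  }
  if (any(par_above <= 0)) {
    stop("invalid reading: par_above must be > 0", call. = FALSE)
  }
  if (any(par_below < 0)) {
    stop("invalid reading: par_below must be >= 0", call. = FALSE)
  }
  f <- (par_above - par_below) / par_above
  if (any(f < 0)) {
    warning(sprintf("%d reading(s) with par_below > par_above clamped to eps",
                    sum(f < 0)), call. = FALSE)
  }
  clamp(f, eps, 1 - eps)
}

#' Cumulative incident PAR from planting
#'
#' Sums daily incident PAR (taken as 45% of daily total solar radiation)
#' from the planting day through `date` inclusive.
#'
#' @inheritParams accumulate_gdd
#' @param date last day of accumulation, inclusive.
#' @param par_fraction PAR fraction of total solar radiation (default 0.45).
#' @return cumulative incident PAR, MJ m-2.
#' @export
cumulative_incident_par <- function(weather, planting_date, date,
                                    par_fraction = 0.45) {
  planting_date <- as.Date(planting_date)
  date <- as.Date(date)
  if (date < planting_date) {
    stop("'date' precedes 'planting_date'", call. = FALSE)
  }
  w <- check_weather(weather)
  if (is.null(w$solar_mj_m2)) {
    stop("weather table lacks column 'solar_mj_m2'", call. = FALSE)
  }
  wanted <- seq(planting_date, date, by = "day")
  idx <- match(wanted, w$date)
  if (anyNA(idx)) {
    missing_day <- wanted[which(is.na(idx))[1L]]
    stop(sprintf("weather gap: no record for %s", format(missing_day)),
         call. = FALSE)
  }
  sum(w$solar_mj_m2[idx]) * par_fraction
}

#' Cumulative intercepted PAR at a sampling date
#'
#' Product of the interception fraction measured on the sampling date
#' and the cumulative incident PAR from planting to that date.
#'
#' @param ipar_f interception fraction in `[0, 1]`.
#' @param cum_par cumulative incident PAR, MJ m-2.
#' @return cumulative IPAR, MJ m-2. Vectorized.
#' @export
cumulative_ipar <- function(ipar_f, cum_par) {
  if (any(ipar_f < 0 | ipar_f > 1)) {
    stop("ipar_f must lie in [0, 1]", call. = FALSE)
  }
  ipar_f * cum_par
}

#' Radiation use efficiency series referenced to the first sampling date
#'
#' `RUE_n = (biomass_n - biomass_1) / (cum_ipar_n - cum_ipar_1)` for each
#' sampling date `n >= 2` of one plot; the first date is the reference
#' point and has no RUE.
#'
#' @param biomass above-ground dry biomass per sampling date, g m-2,
#'   in date order.
#' @param cum_ipar cumulative IPAR per sampling date, MJ m-2; must be
#'   strictly greater than the first date's value for all `n >= 2`.
#' @return numeric vector of the same length; element 1 is `NA`.
#' @export
rue_series <- function(biomass, cum_ipar) {
  n <- length(biomass)
  if (length(cum_ipar) != n) {
    stop("'biomass' and 'cum_ipar' lengths differ", call. = FALSE)
  }
  if (n < 2L) stop("need at least 2 sampling dates", call. = FALSE)
  d_ipar <- cum_ipar[-1L] - cum_ipar[1L]
  if (any(d_ipar == 0)) {
    stop("degenerate denominator: cumulative IPAR equals the reference date's",
         call. = FALSE)
  }
  c(NA_real_, (biomass[-1L] - biomass[1L]) / d_ipar)
}

#' Measured harvest index
#'
#' Lint yield divided by the highest above-ground dry biomass observed
#' during the season, both expressed in kg ha-1 (the factor 10 converts
#' biomass from g m-2).
#'
#' @param lint_yield_kg_ha machine-harvested lint yield, kg ha-1.
#' @param biomass_series_g_m2 per-date biomass, g m-2 (any order).
#' @return harvest index (fraction).
#' @export
measured_hi <- function(lint_yield_kg_ha, biomass_series_g_m2) {
  if (lint_yield_kg_ha < 0) stop("lint yield must be >= 0", call. = FALSE)
  if (!length(biomass_series_g_m2)) {
    stop("empty biomass series", call. = FALSE)
  }
  peak <- max(biomass_series_g_m2)
  if (peak <= 0) stop("degenerate: maximum biomass is zero", call. = FALSE)
  lint_yield_kg_ha / (10 * peak)
}
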