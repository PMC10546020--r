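#' Names of the candidate yield-physiology predictors
#'
#' The twenty vegetation indices plus the five raw band means that are
#' screened as predictors of IPARf, biomass and RUE.
#'
#' @return character vector of 25 predictor names.
#' @export
vi_names <- function() {
  c("ExG", "NDVI", "GNDVI", "NDRE", "RVI", "SCCCI", "SAVI", "EVI", "EVI2",
    "MSAVI", "VARI", "WDRVI", "RECI", "RE/R", "NIR/G", "RGBVI", "GRVI",
    "TCARI", "OSAVI", "TCARI/OSAVI", "BLUE", "GREEN", "RED", "REDEDGE", "NIR")
}

#' Compute a single vegetation index from band means
#'
#' Implements the study's index formulary on mean canopy reflectance.
#' Two formulas are kept exactly as tabulated even though they deviate
#' from the classical literature forms: EVI uses the numerator
#' `2.5 x NIR - R` (not `2.5 x (NIR - R)`; the classical variant is
#' available as `"EVI_classic"`), and RGBVI is
#' `(G - B x R) / (G^2 + B x R)`. Any zero denominator yields `NA`
#' (an undefined marker that downstream fitting drops with a count),
#' never a silent 0.
#'
#' @param bands named numeric vector or one-row data frame with
#'   `blue`, `green`, `red`, `rededge`, `nir` reflectance means.
#' @param name index name from [vi_names()] (plus `"EVI_classic"`).
#' @return unitless scalar, or `NA_real_` where undefined.
#' @export
compute_vi <- function(bands, name) {
  if (is.data.frame(bands)) bands <- unlist(bands[1L, band_names()])
  if (!all(band_names() %in% names(bands))) {
    stop("bands must contain blue, green, red, rededge, nir", call. = FALSE)
  }
  B <- as.numeric(bands[["blue"]]); G <- as.numeric(bands[["green"]])
  R <- as.numeric(bands[["red"]]); RE <- as.numeric(bands[["rededge"]])
  NIR <- as.numeric(bands[["nir"]])
  if (any(!is.finite(c(B, G, R, RE, NIR)))) {
    stop("band values must be finite", call. = FALSE)
  }
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  val <- switch(name,
    "ExG" = 2 * G - R - B,
    "NDVI" = sdiv(NIR - R, NIR + R),
    "GNDVI" = sdiv(NIR - G, NIR + G),
    "NDRE" = sdiv(NIR - RE, NIR + RE),
    "RVI" = sdiv(NIR, R),
    "SCCCI" = {
      ndvi <- sdiv(NIR - R, NIR + R)
      ndre <- sdiv(NIR - RE, NIR + RE)
      if (is.na(ndvi) || is.na(ndre) || ndvi == 0) NA_real_ else ndre / ndvi
    },
    "SAVI" = sdiv(1.5 * (NIR - R), NIR + R + 0.5),
    "EVI" = sdiv(2.5 * NIR - R, NIR + 6 * R - 7.5 * B + 1),
    "EVI_classic" = sdiv(2.5 * (NIR - R), NIR + 6 * R - 7.5 * B + 1),
    "EVI2" = sdiv(2.5 * NIR - R, NIR + 2.5 * R + 1),
    "MSAVI" = {
      disc <- (2 * NIR + 1)^2 - 8 * (NIR - R)
      if (disc < 0) NA_real_ else ((2 * NIR + 1) - sqrt(disc)) / 2
    },
    "VARI" = sdiv(G - R, G + R - B),
    "WDRVI" = sdiv(0.2 * NIR - R, 0.2 * NIR + R),
    "RECI" = if (RE == 0) NA_real_ else NIR / RE - 1,
    "RE/R" = sdiv(RE, R),
    "NIR/G" = sdiv(NIR, G),
    "RGBVI" = sdiv(G - B * R, G^2 + B * R),
    "GRVI" = sdiv(G - R, G + R),
    "TCARI" = if (R == 0) NA_real_ else 3 * ((RE - R) - 0.2 * (RE - G) * (RE / R)),
    "OSAVI" = sdiv(1.16 * (NIR - R), NIR + R + 0.16),
    "TCARI/OSAVI" = {
      tcari <- if (R == 0) NA_real_ else 3 * ((RE - R) - 0.2 * (RE - G) * (RE / R))
      osavi <- sdiv(1.16 * (NIR - R), NIR + R + 0.16)
      if (is.na(tcari) || is.na(osavi) || osavi == 0) NA_real_ else tcari / osavi
    },
    "BLUE" = B, "GREEN" = G, "RED" = R, "REDEDGE" = RE, "NIR" = NIR,
    stop(sprintf("unknown vegetation index '%s'", name), call. = FALSE)
  )
  val
}

#' Compute all 25 predictors from one band-mean record
#'
#' @inheritParams compute_vi
#' @return named numeric vector over [vi_names()].
#' @export
compute_all_vis <- function(bands) {
  vapply(vi_names(), function(nm) compute_vi(bands, nm), numeric(1))
}
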