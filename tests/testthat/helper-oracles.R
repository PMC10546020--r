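# Independent brute-force oracles, deliberately coded as flat formula
# transcriptions without the package's helpers.

bands_vec <- function(B, G, R, RE, NIR) {
  c(blue = B, green = G, red = R, rededge = RE, nir = NIR)
}

oracle_vi <- function(B, G, R, RE, NIR) {
  ndvi <- (NIR - R) / (NIR + R)
  ndre <- (NIR - RE) / (NIR + RE)
  tcari <- 3 * ((RE - R) - 0.2 * (RE - G) * (RE / R))
  osavi <- (1 + 0.16) * (NIR - R) / (NIR + R + 0.16)
  c("ExG" = 2 * G - R - B,
    "NDVI" = ndvi,
    "GNDVI" = (NIR - G) / (NIR + G),
    "NDRE" = ndre,
    "RVI" = NIR / R,
    "SCCCI" = ndre / ndvi,
    "SAVI" = (1 + 0.5) * (NIR - R) / (NIR + R + 0.5),
    "EVI" = (2.5 * NIR - R) / (NIR + 6 * R - 7.5 * B + 1),
    "EVI2" = (2.5 * NIR - R) / (NIR + 2.5 * R + 1),
    "MSAVI" = ((2 * NIR + 1) - sqrt((2 * NIR + 1)^2 - 8 * (NIR - R))) / 2,
    "VARI" = (G - R) / (G + R - B),
    "WDRVI" = (0.2 * NIR - R) / (0.2 * NIR + R),
    "RECI" = NIR / RE - 1,
    "RE/R" = RE / R,
    "NIR/G" = NIR / G,
    "RGBVI" = (G - B * R) / (G^2 + B * R),
    "GRVI" = (G - R) / (G + R),
    "TCARI" = tcari,
    "OSAVI" = osavi,
    "TCARI/OSAVI" = tcari / osavi,
    "BLUE" = B, "GREEN" = G, "RED" = R, "REDEDGE" = RE, "NIR" = NIR)
}

oracle_gdd <- function(tmax, tmin) {
  tm <- if (tmax > 33.9) 33.9 else tmax
  g <- (tm + tmin) / 2 - 15.6
  if (g < 0) 0 else g
}
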