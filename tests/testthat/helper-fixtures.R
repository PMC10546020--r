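# Shared fixtures: endmember spectra, tiny rasters, and the weighted
# factorial layout used by the parameter-recovery studies.

soil_em <- c(blue = 0.08, green = 0.12, red = 0.16, rededge = 0.20,
             nir = 0.24)
canopy_em <- c(blue = 0.03, green = 0.08, red = 0.04, rededge = 0.25,
               nir = 0.45)

# raster with the left half canopy endmember, right half soil endmember
half_canopy_raster <- function(h = 10L, w = 10L) {
  bands <- lapply(band_names(), function(b) {
    m <- matrix(soil_em[[b]], h, w)
    m[, seq_len(w %/% 2)] <- canopy_em[[b]]
    m
  })
  names(bands) <- band_names()
  do.call(multispectral_raster, bands)
}

uniform_raster <- function(em, h = 10L, w = 10L) {
  bands <- lapply(band_names(), function(b) matrix(em[[b]], h, w))
  names(bands) <- band_names()
  do.call(multispectral_raster, bands)
}

rect_roi <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# factorial predictor layout concentrating replication where the beta
# likelihood is least informative, so the interaction is identifiable
recovery_design <- function(n = 250L) {
  g <- expand.grid(vi = c(0, 1), gdd = c(0, 1600))
  idx <- rep(1:4, times = round(n * c(0.32, 0.14, 0.136, 0.404)))[seq_len(n)]
  list(vi = g$vi[idx], gdd = g$gdd[idx])
}

beta_truth <- c(-3, 2.5, 0.002, 0.0005)
phi_truth <- 60
biomass_truth <- c(1.7, 1.5, 0.0017, 0.0008)
alpha_truth <- 25
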