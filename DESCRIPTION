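Package: cottonphys
Title: Cotton Canopy Physiology from UAV Multispectral and RGB Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested pipeline from plot-level multispectral reflectance
    rasters, pre-harvest RGB imagery and daily weather records to the
    physiological drivers of cotton lint yield: fraction of intercepted
    photosynthetically active radiation (IPARf), above-ground biomass,
    radiation use efficiency (RUE), cotton fiber index (CFI) based lint
    yield, and harvest index (HI). Canopy is separated from soil with an
    NDVI x ExG classification index, twenty vegetation indices plus the
    five raw bands are computed per plot, and generalized linear models
    (beta/logit for IPARf, gamma/log for biomass, gaussian/identity for
    RUE) are fitted, ranked by information criteria and cross-validated
    on a date-stratified split. A synthetic-scene generator emulates a
    five-nitrogen-rate by five-block plot trial so every stage is
    testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    glmmTMB,
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
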