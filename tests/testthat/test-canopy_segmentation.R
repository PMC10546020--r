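one_pixel_raster <- function(b, g, r, re, nir) {
  multispectral_raster(matrix(b), matrix(g), matrix(r), matrix(re),
                       matrix(nir))
}

test_that("classification index is NDVI x ExG on reflectance", {
  idx <- classification_index(one_pixel_raster(0.05, 0.2, 0.1, 0.2, 0.5))
  expect_equal(idx[1L, 1L], (0.4 / 0.6) * 0.25, tolerance = 1e-12)

  # NIR == R makes NDVI zero regardless of greenness
  idx <- classification_index(one_pixel_raster(0.05, 0.3, 0.2, 0.2, 0.2))
  expect_equal(idx[1L, 1L], 0)

  # neutral soil endmember: ExG = 2*0.12 - 0.16 - 0.08 = 0 (to rounding)
  idx <- classification_index(uniform_raster(soil_em))
  expect_lt(max(abs(idx)), 1e-15)
  expect_false(any(canopy_mask(idx)))

  # NIR + R = 0 maps to 0 rather than NaN
  idx <- classification_index(one_pixel_raster(0.05, 0.2, 0, 0.2, 0))
  expect_equal(idx[1L, 1L], 0)
})

test_that("canopy mask thresholds strictly and is idempotent", {
  idx <- matrix(c(0.03, 0.02, 0, -0.01), 2L)
  m <- canopy_mask(idx)
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(canopy_mask(idx), m)   # same plane, same mask
  expect_false(any(canopy_mask(matrix(0, 4L, 4L))))
})

test_that("point-in-polygon agrees with an independent implementation", {
  skip_if_not_installed("mgcv")
  set.seed(42)
  for (rep in 1:5) {
    # star-shaped random polygon around a center (simple by construction)
    ang <- sort(runif(7, 0, 2 * pi))
    rad <- runif(7, 2, 10)
    poly <- cbind(10 + rad * cos(ang), 10 + rad * sin(ang))
    px <- runif(200, 0, 20); py <- runif(200, 0, 20)
    mine <- point_in_polygon(px, py, poly)
    ring <- rbind(poly, poly[1L, ])
    oracle <- mgcv::in.out(ring, cbind(px, py))
    expect_equal(mine, as.vector(oracle))
  }
})

test_that("ROI extraction averages canopy pixels only", {
  roi <- rect_roi(1, 1, 9, 9)

  r <- uniform_raster(canopy_em)
  mask <- matrix(TRUE, 10L, 10L)
  bm <- extract_roi_reflectance(r, mask, roi)
  for (b in band_names()) expect_equal(bm[[b]], canopy_em[[b]])

  # 50% canopy / 50% soil with a correct mask: soil never leaks in
  r <- half_canopy_raster()
  mask <- canopy_mask(classification_index(r))
  bm <- extract_roi_reflectance(r, mask, roi)
  for (b in band_names()) expect_equal(bm[[b]], canopy_em[[b]])

  # background pixel edits never change the result
  r2 <- r
  r2[, 6:10, ] <- 0.99
  bm2 <- extract_roi_reflectance(r2, mask, roi)
  expect_equal(bm2[, band_names()], bm[, band_names()])

  # empty canopy: error unless the explicit fallback is requested
  none <- matrix(FALSE, 10L, 10L)
  expect_error(extract_roi_reflectance(r, none, roi), "no canopy")
  bm3 <- extract_roi_reflectance(r, none, roi, allow_unmasked = TRUE)
  expect_gt(bm3$n_canopy_pixels, 0L)
})

test_that("seeded synthetic plot matches a brute-force per-pixel oracle", {
  r <- render_plot_raster(0.5, canopy_em, soil_em, dims = c(20L, 30L),
                          sigma = 0.01, seed = 7)
  idx <- classification_index(r)
  mask <- canopy_mask(idx)
  roi <- cbind(x = c(3, 27, 27, 14, 3), y = c(3, 3, 17, 19, 17))
  bm <- extract_roi_reflectance(r, mask, roi)

  # oracle: explicit double loop with its own crossing-count test
  in_poly <- function(x, y, poly) {
    n <- nrow(poly); hit <- FALSE; j <- n
    for (i in 1:n) {
      if ((poly[i, 2L] > y) != (poly[j, 2L] > y)) {
        xcross <- (poly[j, 1L] - poly[i, 1L]) * (y - poly[i, 2L]) /
          (poly[j, 2L] - poly[i, 2L]) + poly[i, 1L]
        if (x < xcross) hit <- !hit
      }
      j <- i
    }
    hit
  }
  sums <- setNames(numeric(5), band_names()); count <- 0L
  for (i in 1:20) {
    for (j in 1:30) {
      if (mask[i, j] && in_poly(j - 0.5, i - 0.5, roi)) {
        count <- count + 1L
        for (b in band_names()) sums[b] <- sums[b] + r[i, j, b]
      }
    }
  }
  expect_identical(bm$n_canopy_pixels, count)
  for (b in band_names()) {
    expect_equal(bm[[b]], sums[[b]] / count, tolerance = 1e-12)
  }
})

test_that("masked ROI NDVI increases with canopy cover on noiseless scenes", {
  roi <- rect_roi(1, 1, 29, 19)
  ndvi <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(cv) {
    r <- render_plot_raster(cv, canopy_em, soil_em, dims = c(20L, 30L),
                            sigma = 0, seed = 11)
    # unmasked ROI mean mixes soil and canopy in proportion to cover
    bm <- extract_roi_reflectance(r, matrix(TRUE, 20L, 30L), roi)
    compute_vi(bm, "NDVI")
  }, numeric(1))
  expect_true(all(diff(ndvi) > 0))
})

test_that("WKT polygons round-trip", {
  poly <- rect_roi(2, 10, 118, 30)
  back <- parse_wkt_polygon(format_wkt_polygon(poly))
  expect_equal(unname(back), unname(poly))
  expect_error(parse_wkt_polygon("LINESTRING (0 0, 1 1)"), "WKT")
})
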