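test_that("simulated weather is deterministic with the stated structure", {
  w1 <- simulate_weather(150, seed = 1)
  w2 <- simulate_weather(150, seed = 1)
  expect_identical(w1, w2)

  smooth <- simulate_weather(100, seed = 1,
                             noise = c(tmax = 0, tmin = 0, solar = 0))
  expect_equal(smooth$tmax_c - smooth$tmin_c, rep(10, 100))
  expect_equal(smooth$tmax_c,
               32 + 4 * sin(pi * (1:100 - 0.5) / 100), tolerance = 1e-12)

  expect_gt(mean(w1$tmax_c), 28)
  expect_lt(mean(w1$tmax_c), 36)
  expect_true(all(w1$solar_mj_m2 >= 2))
  expect_true(all(w1$tmin_c <= w1$tmax_c))
})

test_that("logistic canopy development respects its parameters", {
  expect_equal(simulate_canopy(700, 179), (0.55 + 0.40) / 2)  # midpoint
  expect_equal(simulate_canopy(1e6, 0), 0.55, tolerance = 1e-6) # asymptote
  g <- c(200, 600, 1000, 1400)
  expect_true(all(simulate_canopy(g, 179) > simulate_canopy(g, 0)))
  expect_error(simulate_canopy(-5, 89), "gdd")
})

test_that("plot rendering hits its cover target and endmembers", {
  r1 <- render_plot_raster(1, canopy_em, soil_em, sigma = 0, seed = 1)
  for (b in band_names()) {
    expect_true(all(r1[, , b] == canopy_em[[b]]))
  }

  r0 <- render_plot_raster(0, canopy_em, soil_em, sigma = 0, seed = 1)
  mask <- canopy_mask(classification_index(r0))
  expect_false(any(mask))   # neutral soil: ExG = 0 everywhere

  r5 <- render_plot_raster(0.5, canopy_em, soil_em, sigma = 0, seed = 2)
  truth <- attr(r5, "canopy_truth")
  expect_lt(abs(mean(truth) - 0.5), 0.02)
  roi <- rect_roi(2, 10, 118, 30)
  bm <- extract_roi_reflectance(r5, truth, roi)
  for (b in band_names()) expect_equal(bm[[b]], canopy_em[[b]])

  expect_identical(render_plot_raster(0.5, canopy_em, soil_em, seed = 9),
                   render_plot_raster(0.5, canopy_em, soil_em, seed = 9))
})

test_that("ground-truth draws concentrate on the generative means", {
  cfg <- sim_config(seed = 1)
  vi <- runif(200, 0.7, 0.9)
  gdd <- runif(200, 300, 1600)

  tight <- sim_config(seed = 1, phi_beta = 1e6)
  gt <- simulate_ground_truth(vi, gdd, tight, seed = 2)
  expect_lt(max(abs(gt$ipar_f_obs - gt$ipar_f_true)), 1e-2)

  flat <- sim_config(seed = 1, beta_ipar = c(0, 0, 0, 0))
  gf <- simulate_ground_truth(vi, gdd, flat, seed = 2)
  expect_equal(gf$ipar_f_true, rep(0.5, 200))

  bad <- sim_config(seed = 1)
  bad$beta_ipar <- c(1, 2)
  expect_error(simulate_ground_truth(vi, gdd, bad, seed = 2),
               "4 coefficients")
})

test_that("harvest rendering ties boll area to yield", {
  cfg <- sim_config(seed = 1, n_veg_blobs = 0L)
  z <- render_harvest_rgb(0, cfg, seed = 3)
  expect_equal(z$true_cfi, 0)
  enh <- enhance_image(z$img)
  expect_equal(compute_cfi(enh)$cfi, 0)

  expect_identical(render_harvest_rgb(3000, cfg, seed = 4),
                   render_harvest_rgb(3000, cfg, seed = 4))

  # doubling yield doubles the expected painted area (Poisson mean)
  cfis <- vapply(1:30, function(s) {
    c(render_harvest_rgb(1500, cfg, seed = s)$true_cfi,
      render_harvest_rgb(3000, cfg, seed = 100 + s)$true_cfi)
  }, numeric(2))
  expect_equal(mean(cfis[2, ]) / mean(cfis[1, ]), 2, tolerance = 0.25)
})

test_that("the study bundle has the declared shape and determinism", {
  cfg <- sim_config(seed = 6)
  st <- generate_study(cfg)
  expect_equal(nrow(st$samples), 125L)          # 25 plots x 5 dates
  expect_length(st$rasters, 125L)
  expect_length(st$harvest, 25L)
  expect_equal(nrow(st$plots), 25L)

  # truth ledger max-biomass semantics
  for (pid in st$plots$plot_id) {
    expect_gte(st$plots$max_biomass_true[st$plots$plot_id == pid],
               max(st$samples$biomass_true[st$samples$plot_id == pid]))
  }
  # interception equation round-trips through the PAR readings
  expect_equal(ipar_fraction(st$samples$par_above, st$samples$par_below),
               st$samples$ipar_f_obs, tolerance = 1e-9)

  # same seed, byte-identical CSV outputs
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(), "study_b")
  generate_study(cfg, out_dir = d1)
  generate_study(cfg, out_dir = d2)
  for (f in c("weather.csv", "ground.csv", "rois.csv", "truth.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("unknown config fields are rejected", {
  expect_error(sim_config(seed = 1, foo = 3), "foo")
  expect_error(sim_config(seed = 1, phi_beta = -2), "positive")
})
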