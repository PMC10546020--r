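# Synthetic study generator: a 5-nitrogen-rate x 5-block plot trial
# sampled 5 times over a 150-day season, with the statistical structure
# the analysis assumes -- beta-distributed IPARf with a logit mean in VI
# and GDD, gamma-distributed biomass with a log mean, and lint yield
# proportional to boll area in the harvest image. Everything is
# deterministic given the root seed.

#' Default synthetic-study configuration
#'
#' Study conditions: 5 nitrogen rates (0, 44, 89, 135, 179 kg N ha-1) x
#' 5 blocks in a randomized complete block layout, 5 sampling dates, a
#' 150-day season. Generative coefficients place the beta/logit IPARf
#' mean and the gamma/log biomass mean on realistic cotton trajectories
#' over the sampled GDD range; endmember spectra are invented,
#' documented constants (config, not claims).
#'
#' @param seed root seed; all stage sub-seeds derive from it.
#' @param ... overrides for any default field (unknown names rejected).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    n_blocks = 5L,
    n_rates = c(0, 44, 89, 135, 179),      # kg N ha-1
    n_dates = 5L,
    season_length_days = 150L,
    planting_date = as.Date("2022-05-01"),
    sampling_dap = NULL,                   # default: evenly spaced 40..124
    plot_px = c(40L, 120L),                # rows x cols of a plot raster
    n_crop_rows = 4L,
    soil_endmember = c(blue = 0.08, green = 0.12, red = 0.16,
                       rededge = 0.20, nir = 0.24),
    canopy_endmember = c(blue = 0.03, green = 0.08, red = 0.06,
                         rededge = 0.25, nir = 0.45),
    red_n_drop = 0.03,       # canopy red falls by this from N=0 to N=max
    band_noise_sd = 0.01,
    c_base = 0.55, c_span = 0.40,          # max canopy cover vs N rate
    k_g = 0.004, g_mid = 700,              # logistic growth in GDD
    beta_ipar = c(-3, 2.5, 0.002, 0.0005), # logit-scale (1, VI, GDD, VI*GDD)
    phi_beta = 60,
    beta_biomass = c(1.7, 1.5, 0.0017, 0.0008), # log-scale (1, VI, GDD, VI*GDD)
    alpha_gamma = 25,
    hi_mean = 0.4, hi_sd = 0.03,           # truth HI ~ trunc-normal (0.2,0.6)
    yield_noise_sd = 100,                  # kg ha-1 harvest measurement noise
    par_above = 2000,
    harvest_px = c(100L, 240L),
    boll_rate = 0.05,                      # bolls per kg ha-1 per plot
    boll_radius = c(2L, 4L),
    boll_intensity = c(235, 8),            # mean, sd (8-bit)
    n_veg_blobs = 25L,
    weather_noise = c(tmax = 2, tmin = 1.5, solar = 3)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  if (is.null(cfg$sampling_dap)) {
    cfg$sampling_dap <- round(seq(40, 124, length.out = cfg$n_dates))
  }
  cfg$planting_date <- as.Date(cfg$planting_date)
  if (cfg$phi_beta <= 0 || cfg$alpha_gamma <= 0 || cfg$band_noise_sd < 0) {
    stop("dispersion and noise parameters must be positive", call. = FALSE)
  }
  if (cfg$c_base + cfg$c_span > 1 || cfg$c_base <= 0) {
    stop("canopy cover asymptote must lie in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a season of daily weather
#'
#' Sinusoidal seasonal courses with gaussian noise:
#' `tmax = 32 + 4 sin(phase) + N(0, 2)` degC,
#' `tmin = tmax - 10 + N(0, 1.5)` (clipped to `tmin <= tmax`),
#' `solar = 18 + 6 sin(phase) + N(0, 3)` MJ m-2 d-1 (clipped >= 2),
#' where the phase runs half a cycle over the season so conditions peak
#' mid-season. Deterministic per seed.
#'
#' @param n_days season length in days.
#' @param seed integer seed.
#' @param planting_date date of day 1.
#' @param noise named vector `c(tmax=, tmin=, solar=)` of noise SDs.
#' @return weather data frame (`date`, `tmax_c`, `tmin_c`,
#'   `solar_mj_m2`).
#' @export
simulate_weather <- function(n_days, seed = 1L,
                             planting_date = as.Date("2022-05-01"),
                             noise = c(tmax = 2, tmin = 1.5, solar = 3)) {
  if (n_days < 1L) stop("n_days must be >= 1", call. = FALSE)
  phase <- pi * (seq_len(n_days) - 0.5) / n_days
  with_seed(seed, {
    tmax <- 32 + 4 * sin(phase) + stats::rnorm(n_days, 0, noise[["tmax"]])
    tmin <- tmax - 10 + stats::rnorm(n_days, 0, noise[["tmin"]])
    tmin <- pmin(tmin, tmax)
    solar <- pmax(2, 18 + 6 * sin(phase) +
                    stats::rnorm(n_days, 0, noise[["solar"]]))
    data.frame(date = as.Date(planting_date) + seq_len(n_days) - 1L,
               tmax_c = tmax, tmin_c = tmin, solar_mj_m2 = solar)
  })
}

#' Logistic canopy-cover development
#'
#' `cover = c_max(N) / (1 + exp(-k_g (GDD - g_mid)))` with the asymptote
#' increasing linearly in nitrogen rate:
#' `c_max = c_base + c_span * n_rate / max_rate`.
#'
#' @param gdd accumulated growing degree days (>= 0). Vectorized.
#' @param n_rate nitrogen rate, kg N ha-1.
#' @param c_base,c_span,k_g,g_mid growth parameters (see [sim_config()]).
#' @param max_rate nitrogen rate at which the asymptote span is fully
#'   realized (default 179).
#' @return canopy cover fraction in `(0, 1)`.
#' @export
simulate_canopy <- function(gdd, n_rate, c_base = 0.55, c_span = 0.40,
                            k_g = 0.004, g_mid = 700, max_rate = 179) {
  if (any(gdd < 0)) stop("gdd must be >= 0", call. = FALSE)
  c_max <- c_base + c_span * n_rate / max_rate
  c_max / (1 + exp(-k_g * (gdd - g_mid)))
}

# Per-nitrogen-rate canopy endmember: red reflectance falls with N
# (chlorophyll proxy), other bands fixed.
canopy_endmember_for <- function(cfg, n_rate) {
  em <- cfg$canopy_endmember
  em[["red"]] <- em[["red"]] - cfg$red_n_drop * n_rate / max(cfg$n_rates)
  em
}

#' Render a synthetic plot raster
#'
#' Assigns exactly `round(cover * npixels)` pixels to canopy, favouring
#' pixels near the crop-row strips (weighted sampling without
#' replacement over a gaussian row-strip profile), then draws each
#' pixel's five bands as its endmember plus `N(0, sigma)` noise. With
#' `sigma = 0` and `cover = 1` every pixel equals the canopy endmember
#' exactly.
#'
#' @param cover canopy cover fraction in `[0, 1]`.
#' @param canopy_em,soil_em named 5-band endmember vectors.
#' @param dims `c(rows, cols)` of the plot raster.
#' @param n_crop_rows number of crop-row strips.
#' @param sigma per-band gaussian noise SD.
#' @param seed integer seed.
#' @return 5-band raster array with attribute `canopy_truth` (logical
#'   matrix of the rendered canopy pixels).
#' @export
render_plot_raster <- function(cover, canopy_em, soil_em,
                               dims = c(40L, 120L), n_crop_rows = 4L,
                               sigma = 0.01, seed = 1L) {
  if (cover < 0 || cover > 1) stop("cover must lie in [0, 1]", call. = FALSE)
  h <- dims[1L]; w <- dims[2L]
  npix <- h * w
  centers <- (seq_len(n_crop_rows) - 0.5) * h / n_crop_rows
  y <- seq_len(h) - 0.5
  wt_row <- rowSums(vapply(centers,
                           function(c0) exp(-(y - c0)^2 / (2 * 3^2)),
                           numeric(h)))
  wt <- matrix(wt_row / mean(wt_row), nrow = h, ncol = w)
  k <- round(cover * npix)
  with_seed(seed, {
    canopy <- matrix(FALSE, h, w)
    if (k > 0L) {
      key <- log(stats::runif(npix)) / as.vector(wt)
      canopy[order(key, decreasing = TRUE)[seq_len(k)]] <- TRUE
    }
    bands <- lapply(band_names(), function(b) {
      m <- matrix(soil_em[[b]], h, w)
      m[canopy] <- canopy_em[[b]]
      if (sigma > 0) m <- m + matrix(stats::rnorm(npix, 0, sigma), h, w)
      m
    })
    names(bands) <- band_names()
    r <- suppressWarnings(do.call(multispectral_raster, bands))
    attr(r, "canopy_truth") <- canopy
    r
  })
}

#' Draw ground-truth physiology for plot x date records
#'
#' Generative mirror of the model forms fitted downstream: the IPARf
#' mean is `plogis(b0 + b1 VI + b2 GDD + b3 VI GDD)` with beta noise at
#' precision `phi`; the biomass mean is the same linear predictor
#' exponentiated (its own coefficients) with gamma noise at shape
#' `alpha`.
#'
#' @param vi generative vegetation-index value per record.
#' @param gdd growing degree days per record.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data frame: `ipar_f_true` (mean), `ipar_f_obs`,
#'   `biomass_true` (mean, g m-2), `biomass_obs`.
#' @export
simulate_ground_truth <- function(vi, gdd, config, seed = 1L) {
  if (length(vi) != length(gdd)) {
    stop("vi and gdd lengths differ", call. = FALSE)
  }
  for (nm in c("beta_ipar", "beta_biomass")) {
    if (length(config[[nm]]) != 4L) {
      stop(sprintf("config$%s must have 4 coefficients", nm), call. = FALSE)
    }
  }
  X <- cbind(1, vi, gdd, vi * gdd)
  mu_i <- stats::plogis(drop(X %*% config$beta_ipar))
  mu_b <- exp(drop(X %*% config$beta_biomass))
  phi <- config$phi_beta
  alpha <- config$alpha_gamma
  with_seed(seed, {
    ipar_obs <- stats::rbeta(length(vi), mu_i * phi, (1 - mu_i) * phi)
    bio_obs <- stats::rgamma(length(vi), shape = alpha, rate = alpha / mu_b)
    data.frame(ipar_f_true = mu_i,
               ipar_f_obs = clamp(ipar_obs, 1e-6, 1 - 1e-6),
               biomass_true = mu_b, biomass_obs = bio_obs)
  })
}

paint_disk <- function(h, w, cy, cx, r) {
  rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  grid <- expand.grid(row = rows, col = cols)
  hit <- (grid$row - cy)^2 + (grid$col - cx)^2 <= r^2
  cbind(grid$row[hit], grid$col[hit])
}

#' Render a synthetic pre-harvest RGB image
#'
#' Soil background `N(100, 10)` per channel, defoliated-vegetation blobs
#' `N(130, 10)`, and near-achromatic boll disks (radius 2-4 px,
#' intensity `N(235, 8)` clipped at 255) whose count is Poisson with
#' mean `boll_rate * yield`. The painted boll-pixel fraction is recorded
#' as the true CFI.
#'
#' @param lint_yield_kg_ha plot lint yield driving the boll count.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list: `img` (`h x w x 3`, 0-255), `boll_mask` (logical),
#'   `true_cfi`.
#' @export
render_harvest_rgb <- function(lint_yield_kg_ha, config, seed = 1L) {
  if (lint_yield_kg_ha < 0) stop("yield must be >= 0", call. = FALSE)
  h <- config$harvest_px[1L]; w <- config$harvest_px[2L]
  with_seed(seed, {
    img <- array(stats::rnorm(h * w * 3, 100, 10), dim = c(h, w, 3L))
    for (i in seq_len(config$n_veg_blobs)) {
      px <- paint_disk(h, w, stats::runif(1, 1, h), stats::runif(1, 1, w),
                       stats::runif(1, 3, 6))
      for (ch in 1:3) {
        img[cbind(px, ch)] <- stats::rnorm(nrow(px), 130, 10)
      }
    }
    boll_mask <- matrix(FALSE, h, w)
    n_bolls <- stats::rpois(1L, config$boll_rate * lint_yield_kg_ha)
    for (i in seq_len(n_bolls)) {
      r <- sample(seq(config$boll_radius[1L], config$boll_radius[2L]), 1L)
      px <- paint_disk(h, w, stats::runif(1, 1, h), stats::runif(1, 1, w), r)
      intensity <- min(255, stats::rnorm(1, config$boll_intensity[1L],
                                         config$boll_intensity[2L]))
      for (ch in 1:3) {
        img[cbind(px, ch)] <- intensity + stats::rnorm(nrow(px), 0, 3)
      }
      boll_mask[px] <- TRUE
    }
    img <- clamp(img, 0, 255)
    list(img = img, boll_mask = boll_mask, true_cfi = mean(boll_mask))
  })
}

# ROI polygon covering the middle two crop rows of a plot raster.
middle_rows_roi <- function(dims = c(40L, 120L), n_crop_rows = 4L,
                            margin = 2) {
  h <- dims[1L]; w <- dims[2L]
  strip_h <- h / n_crop_rows
  y0 <- strip_h * (n_crop_rows / 2 - 1)
  y1 <- strip_h * (n_crop_rows / 2 + 1)
  cbind(x = c(margin, w - margin, w - margin, margin),
        y = c(y0, y0, y1, y1))
}

#' Generate the full synthetic study
#'
#' Produces everything the pipeline consumes: daily weather, the GDD
#' series, per-plot-per-date multispectral rasters with the ROI table,
#' ground measurements (PAR above/below back-computed from the drawn
#' IPARf so the interception equation round-trips exactly, biomass,
#' lint yield), pre-harvest RGB images, and the truth ledger used by
#' recovery tests. Fully deterministic per `config$seed`; sub-seeds are
#' derived per stage (1 weather, 2 physiology, 3 harvest measurement,
#' 100+ rasters, 500+ harvest images).
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes `weather.csv`,
#'   `ground.csv`, `rois.csv`, `truth.json`, per-band raster TIFFs and
#'   harvest PNGs.
#' @return list of class `cotton_study`: `config`, `weather`, `thermal`,
#'   `plots`, `samples`, `rasters`, `rois`, `harvest`.
#' @export
generate_study <- function(config = sim_config(), out_dir = NULL) {
  if (!inherits(config, "sim_config")) {
    stop("config must come from sim_config()", call. = FALSE)
  }
  seed <- config$seed
  weather <- simulate_weather(config$season_length_days,
                              seed = derive_seed(seed, 1L),
                              planting_date = config$planting_date,
                              noise = config$weather_noise)
  season_end <- config$planting_date + config$season_length_days - 1L
  thermal <- accumulate_gdd(weather, config$planting_date, season_end)

  plots <- expand.grid(block = seq_len(config$n_blocks),
                       n_rate = config$n_rates)
  plots$plot_id <- sprintf("B%dN%03d", plots$block, plots$n_rate)
  dates <- config$planting_date + config$sampling_dap

  samples <- merge(plots, data.frame(date = dates,
                                     dap = config$sampling_dap))
  samples <- samples[order(samples$plot_id, samples$date), ]
  rownames(samples) <- NULL
  samples$gdd <- thermal$cumulative_gdd[match(samples$date, thermal$date)]
  samples$cum_par <- vapply(samples$date, function(d) {
    cumulative_incident_par(weather, config$planting_date, d)
  }, numeric(1))
  samples$cover <- simulate_canopy(samples$gdd, samples$n_rate,
                                   c_base = config$c_base,
                                   c_span = config$c_span,
                                   k_g = config$k_g, g_mid = config$g_mid,
                                   max_rate = max(config$n_rates))
  # generative predictor: NDVI of the per-N canopy endmember
  samples$vi_true <- vapply(samples$n_rate, function(nr) {
    compute_vi(canopy_endmember_for(config, nr), "NDVI")
  }, numeric(1))

  truth <- simulate_ground_truth(samples$vi_true, samples$gdd, config,
                                 seed = derive_seed(seed, 2L))
  samples <- cbind(samples, truth)
  samples$par_above <- config$par_above
  samples$par_below <- (1 - samples$ipar_f_obs) * config$par_above

  rasters <- vector("list", nrow(samples))
  names(rasters) <- paste(samples$plot_id, samples$date, sep = "_")
  for (i in seq_len(nrow(samples))) {
    rasters[[i]] <- render_plot_raster(
      samples$cover[i],
      canopy_em = canopy_endmember_for(config, samples$n_rate[i]),
      soil_em = config$soil_endmember,
      dims = config$plot_px, n_crop_rows = config$n_crop_rows,
      sigma = config$band_noise_sd, seed = derive_seed(seed, 100L + i))
  }
  roi <- middle_rows_roi(config$plot_px, config$n_crop_rows)
  rois <- stats::setNames(rep(list(roi), nrow(plots)), plots$plot_id)

  # per-plot season truth: HI, lint yield, harvest imagery
  peak <- vapply(split(samples$biomass_true, samples$plot_id), max,
                 numeric(1))
  plots <- plots[order(plots$plot_id), ]
  rownames(plots) <- NULL
  plots$max_biomass_true <- peak[plots$plot_id]
  harvest_meta <- with_seed(derive_seed(seed, 3L), {
    hi <- stats::rnorm(nrow(plots), config$hi_mean, config$hi_sd)
    while (any(hi <= 0.2 | hi >= 0.6)) {
      bad <- hi <= 0.2 | hi >= 0.6
      hi[bad] <- stats::rnorm(sum(bad), config$hi_mean, config$hi_sd)
    }
    list(hi = hi, noise = stats::rnorm(nrow(plots), 0, config$yield_noise_sd))
  })
  plots$hi_true <- harvest_meta$hi
  plots$lint_yield_true <- plots$hi_true * 10 * plots$max_biomass_true
  plots$lint_yield_meas <- pmax(0, plots$lint_yield_true + harvest_meta$noise)

  harvest <- vector("list", nrow(plots))
  names(harvest) <- plots$plot_id
  for (i in seq_len(nrow(plots))) {
    harvest[[i]] <- render_harvest_rgb(plots$lint_yield_true[i], config,
                                       seed = derive_seed(seed, 500L + i))
  }
  plots$true_cfi <- vapply(harvest, function(hh) hh$true_cfi, numeric(1))

  study <- structure(list(config = config, weather = weather,
                          thermal = thermal, plots = plots,
                          samples = samples, rasters = rasters,
                          rois = rois, harvest = harvest),
                     class = "cotton_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.cotton_study <- function(x, ...) {
  cat(sprintf(
    "cotton_study: %d plots x %d dates (seed %s), season %s + %d days\n",
    nrow(x$plots), length(unique(x$samples$date)),
    format(x$config$seed), format(x$config$planting_date),
    x$config$season_length_days))
  invisible(x)
}

# Write the study bundle in the external formats the pipeline declares.
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$weather, file.path(out_dir, "weather.csv"),
                   row.names = FALSE)
  ground <- study$samples[, c("plot_id", "date", "par_above", "par_below")]
  ground$biomass_g_m2 <- study$samples$biomass_obs
  ground$lint_yield_kg_ha <- NA_real_
  harvest_rows <- data.frame(
    plot_id = study$plots$plot_id,
    date = study$config$planting_date + study$config$season_length_days - 1L,
    par_above = NA_real_, par_below = NA_real_, biomass_g_m2 = NA_real_,
    lint_yield_kg_ha = study$plots$lint_yield_meas)
  utils::write.csv(rbind(ground, harvest_rows),
                   file.path(out_dir, "ground.csv"), row.names = FALSE)
  utils::write.csv(data.frame(
    plot_id = names(study$rois),
    wkt = vapply(study$rois, format_wkt_polygon, character(1))),
    file.path(out_dir, "rois.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(plots = study$plots,
         samples = study$samples[, c("plot_id", "date", "gdd", "cover",
                                     "vi_true", "ipar_f_true", "ipar_f_obs",
                                     "biomass_true", "biomass_obs")]),
    file.path(out_dir, "truth.json"), dataframe = "rows", digits = NA,
    auto_unbox = TRUE)
  ras_dir <- file.path(out_dir, "rasters")
  dir.create(ras_dir, showWarnings = FALSE)
  for (key in names(study$rasters)) {
    r <- study$rasters[[key]]
    for (b in band_names()) {
      tiff::writeTIFF(clamp(r[, , b], 0, 1),
                      file.path(ras_dir, sprintf("%s_%s.tif", key, b)),
                      bits.per.sample = 32L)
    }
  }
  hv_dir <- file.path(out_dir, "harvest")
  dir.create(hv_dir, showWarnings = FALSE)
  for (pid in names(study$harvest)) {
    png::writePNG(study$harvest[[pid]]$img / 255,
                  file.path(hv_dir, sprintf("%s.png", pid)))
  }
  invisible(out_dir)
}
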