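# End-to-end orchestration: segmentation -> band means -> vegetation
# indices -> radiation budget -> GLM screening for the three responses
# -> CFI yield model -> mechanistic RUE -> harvest index.

#' Pipeline configuration
#'
#' Fixed analysis constants with their defaults: segmentation threshold
#' 0.02 on the NDVI x ExG index, white-pixel threshold 150, PAR fraction
#' 0.45 of solar radiation, GDD base 15.6 degC and ceiling 33.9 degC,
#' 60/40 date-stratified split, IQR outlier factor 1.5. Unknown keys are
#' rejected.
#'
#' @param ... overrides for any default field.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seg_threshold = 0.02,
    cfi_threshold = 150,
    par_fraction = 0.45,
    base_temp = 15.6,
    ceiling_temp = 33.9,
    train_fraction = 0.6,
    outlier_factor = 1.5,
    seed = 1L,
    eps = 1e-6,
    terms = c("intercept", "vi", "gdd", "vi_gdd"),
    rue_terms = c("intercept", "vi"),
    predictors = vi_names(),
    allow_unmasked = FALSE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  for (f in c("train_fraction")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) {
      stop(sprintf("'%s' must lie in (0, 1)", f), call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Segment rasters and extract per-plot predictor records
#'
#' For every plot x date raster: classification index, canopy mask at
#' the configured threshold, canopy-masked ROI band means, then all 25
#' predictors.
#'
#' @param study a `cotton_study` bundle (or any list with `samples`,
#'   `rasters`, `rois` of the same shape).
#' @param config a [pipeline_config()].
#' @return data frame: `plot_id`, `date`, the five band means,
#'   `n_canopy_pixels`, and one column per predictor in [vi_names()].
#' @export
extract_features <- function(study, config = pipeline_config()) {
  samples <- study$samples
  rows <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    key <- paste(samples$plot_id[i], samples$date[i], sep = "_")
    raster <- study$rasters[[key]]
    if (is.null(raster)) stop(sprintf("no raster '%s'", key), call. = FALSE)
    idx <- classification_index(raster)
    mask <- canopy_mask(idx, threshold = config$seg_threshold)
    bm <- extract_roi_reflectance(raster, mask,
                                  study$rois[[samples$plot_id[i]]],
                                  allow_unmasked = config$allow_unmasked)
    vis <- compute_all_vis(bm)
    row <- cbind(data.frame(plot_id = samples$plot_id[i],
                            date = samples$date[i]),
                 bm, as.data.frame(as.list(vis), check.names = FALSE,
                                   col.names = names(vis)))
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble plot x date observations
#'
#' Joins the image-derived predictors with the ground measurements and
#' the radiation budget: IPARf from the PAR readings, cumulative IPAR as
#' its product with cumulative incident PAR, and the per-plot measured
#' RUE series referenced to the first sampling date.
#'
#' @param study a `cotton_study` bundle.
#' @param features output of [extract_features()].
#' @param config a [pipeline_config()].
#' @return data frame with one row per plot x date carrying `gdd`,
#'   `cum_par`, `ipar_f`, `cum_ipar`, `biomass`, `rue` and the predictor
#'   columns.
#' @export
assemble_observations <- function(study, features,
                                  config = pipeline_config()) {
  obs <- merge(study$samples[, c("plot_id", "date", "gdd", "cum_par",
                                 "par_above", "par_below", "biomass_obs")],
               features, by = c("plot_id", "date"))
  obs <- obs[order(obs$plot_id, obs$date), ]
  rownames(obs) <- NULL
  obs$ipar_f <- ipar_fraction(obs$par_above, obs$par_below, eps = config$eps)
  obs$cum_ipar <- cumulative_ipar(obs$ipar_f, obs$cum_par)
  names(obs)[names(obs) == "biomass_obs"] <- "biomass"
  obs$rue <- NA_real_
  for (pid in unique(obs$plot_id)) {
    rows <- which(obs$plot_id == pid)
    obs$rue[rows] <- rue_series(obs$biomass[rows], obs$cum_ipar[rows])
  }
  obs
}

# RUE modeling records: dates 2..n per plot, each predictor replaced by
# its average over the RUE calculation period (dates 1..n).
rue_records <- function(obs, predictors = vi_names()) {
  parts <- lapply(split(obs, obs$plot_id), function(d) {
    d <- d[order(d$date), ]
    for (p in predictors) {
      d[[p]] <- cumsum(d[[p]]) / seq_len(nrow(d))
    }
    d[-1L, , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on a study bundle
#'
#' Sequences feature extraction, the radiation budget, outlier removal,
#' the date-stratified split, predictor screening for the three
#' responses (beta/logit IPARf, gamma/log biomass, gaussian/identity
#' RUE), the CFI-based lint-yield model, mechanistic RUE (modeled and
#' measured biomass variants), and the harvest-index evaluation.
#'
#' @param study a `cotton_study` bundle.
#' @param config a [pipeline_config()].
#' @return list with `features`, `observations`, `scores` (one ranked
#'   table per response), `best` (best fitted model per response),
#'   `outliers` (rows removed per response), `cfi` (per-plot table),
#'   `yield_model`, `rue_mech`, `hi`, and `config`.
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  features <- extract_features(study, config)
  obs <- assemble_observations(study, features, config)

  screen_one <- function(data, response_col, family, terms) {
    flt <- remove_outliers(data, response_col, factor = config$outlier_factor)
    spl <- stratified_split(flt$data, date_col = "date",
                            train_fraction = config$train_fraction,
                            seed = config$seed)
    res <- screen_predictors(spl$train, spl$validation, response_col,
                             family = family,
                             predictors = config$predictors, terms = terms)
    res$removed <- flt$removed
    res$train <- spl$train
    res$validation <- spl$validation
    res
  }

  ipar <- screen_one(obs, "ipar_f", "beta", config$terms)
  biomass <- screen_one(obs, "biomass", "gamma", config$terms)
  rue_data <- rue_records(obs, config$predictors)
  rue <- screen_one(rue_data, "rue", "gaussian", config$rue_terms)

  best <- list(ipar_f = ipar$models[[ipar$scores$predictor[1L]]],
               biomass = biomass$models[[biomass$scores$predictor[1L]]],
               rue = rue$models[[rue$scores$predictor[1L]]])

  # CFI chain and yield model on the harvest imagery
  cfi_rows <- lapply(names(study$harvest), function(pid) {
    enh <- enhance_image(study$harvest[[pid]]$img)
    cbind(data.frame(plot_id = pid),
          compute_cfi(enh, roi = NULL, threshold = config$cfi_threshold))
  })
  cfi_tab <- do.call(rbind, cfi_rows)
  cfi_tab <- merge(cfi_tab,
                   study$plots[, c("plot_id", "lint_yield_meas", "true_cfi")],
                   by = "plot_id")
  yield_model <- fit_yield_model(cfi_tab$cfi, cfi_tab$lint_yield_meas)

  # mechanistic RUE: modeled biomass and measured-biomass variants
  rue_mech_modeled <- mechanistic_rue(obs, best$ipar_f, best$biomass)
  rue_mech_measured <- mechanistic_rue(obs, best$ipar_f,
                                       use_measured_biomass = TRUE)

  # harvest index per plot
  hi_rows <- lapply(split(obs, obs$plot_id), function(d) {
    d <- d[order(d$date), ]
    pid <- d$plot_id[1L]
    bm_pred <- predict_response(best$biomass,
                                vi = d[[best$biomass$predictor_vi]],
                                gdd = d$gdd)
    cfi_val <- cfi_tab$cfi[cfi_tab$plot_id == pid]
    yield_pred <- predict_yield(yield_model, cfi_val)
    data.frame(plot_id = pid, season = "S1",
               hi_pred = predict_hi(yield_pred, bm_pred),
               hi_meas = measured_hi(
                 study$plots$lint_yield_meas[study$plots$plot_id == pid],
                 d$biomass))
  })
  hi_estimates <- do.call(rbind, hi_rows)
  rownames(hi_estimates) <- NULL

  list(features = features,
       observations = obs,
       scores = list(ipar_f = ipar$scores, biomass = biomass$scores,
                     rue = rue$scores),
       best = best,
       outliers = list(ipar_f = ipar$removed, biomass = biomass$removed,
                       rue = rue$removed),
       cfi = cfi_tab,
       yield_model = yield_model,
       rue_mech = list(modeled = rue_mech_modeled,
                       measured_biomass = rue_mech_measured),
       hi = list(estimates = hi_estimates,
                 evaluation = evaluate_hi(hi_estimates)),
       config = config)
}

#' Write a ranked score table
#'
#' CSV with columns `predictor, r2, aicc, bic, r2cv, rmsecv, rank` in
#' ranked order; values round-trip through the file at full precision.
#'
#' @param scores ranked score table from [rank_models()].
#' @param path output CSV path.
#' @export
write_score_table <- function(scores, path) {
  if (!nrow(scores)) stop("empty score table", call. = FALSE)
  if (is.null(scores$rank)) scores <- rank_models(scores)
  utils::write.csv(
    scores[, c("predictor", "r2", "aicc", "bic", "r2cv", "rmsecv", "rank")],
    path, row.names = FALSE)
  invisible(path)
}
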