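# Model screening protocol: IQR outlier removal on the pooled data,
# a date-stratified 60/40 train/validation split, likelihood-based
# training scores (generalized R^2, AICc, BIC) and predicted-vs-measured
# cross-validation scores (R^2cv, RMSEcv), then ranking.

#' Interquartile-range outlier removal
#'
#' Flags records whose response lies outside
#' `[Q1 - factor * IQR, Q3 + factor * IQR]`, with quartiles from the
#' type-7 (linear interpolation) quantile rule, computed once over the
#' pooled pre-split data.
#'
#' @param data data frame.
#' @param response_col name of the response column.
#' @param factor IQR multiplier (default 1.5).
#' @return list with `data` (kept rows), `removed` (dropped rows),
#'   and `bounds`.
#' @export
remove_outliers <- function(data, response_col, factor = 1.5) {
  y <- data[[response_col]]
  if (is.null(y)) {
    stop(sprintf("no column '%s'", response_col), call. = FALSE)
  }
  if (sum(is.finite(y)) < 4L) {
    stop("need at least 4 finite responses", call. = FALSE)
  }
  q <- stats::quantile(y, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  lo <- q[1L] - factor * iqr
  hi <- q[2L] + factor * iqr
  out <- is.finite(y) & (y < lo | y > hi)
  list(data = data[!out, , drop = FALSE],
       removed = data[out, , drop = FALSE],
       bounds = c(lower = lo, upper = hi))
}

#' Date-stratified train/validation split
#'
#' Within each sampling date, a seeded random partition assigns
#' `round(train_fraction * n)` records to training and the remainder to
#' validation; a stratum of size 1 goes to training. The caller's RNG
#' state is left untouched.
#'
#' @param data data frame with a sampling-date column.
#' @param date_col stratification column name (default `"date"`).
#' @param train_fraction training share (default 0.6).
#' @param seed integer seed; the split is deterministic given it.
#' @return list with data frames `train` and `validation`.
#' @export
stratified_split <- function(data, date_col = "date", train_fraction = 0.6,
                             seed = 1L) {
  if (is.null(data[[date_col]])) {
    stop(sprintf("no column '%s'", date_col), call. = FALSE)
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  }
  strata <- split(seq_len(nrow(data)), as.character(data[[date_col]]))
  train_idx <- with_seed(seed, {
    unlist(lapply(strata, function(idx) {
      n <- length(idx)
      if (n == 1L) return(idx)
      k <- round(train_fraction * n)
      k <- min(max(k, 1L), n - 1L)
      sort(sample(idx, k))
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = data[train_idx, , drop = FALSE],
       validation = data[setdiff(seq_len(nrow(data)), train_idx), ,
                         drop = FALSE])
}

#' Training-data model scores
#'
#' Likelihood-based scores against the intercept-only null model fitted
#' on the same data: the generalized (Nagelkerke) coefficient of
#' determination
#' `R^2 = (1 - exp(-(2/n)(l1 - l0))) / (1 - exp((2/n) l0))`,
#' the small-sample-corrected Akaike criterion
#' `AICc = -2 l1 + 2k + 2k(k+1)/(n-k-1)` and
#' `BIC = -2 l1 + k log n`, where `k` counts the mean coefficients plus
#' the dispersion parameter.
#'
#' @param model fitted `cotton_glm`.
#' @param null_model intercept-only `cotton_glm` of the same family and
#'   data.
#' @return named vector `c(r2, aicc, bic)`.
#' @export
score_train <- function(model, null_model) {
  if (model$n != null_model$n) {
    stop("model and null model were fitted on different n", call. = FALSE)
  }
  n <- model$n
  k <- length(model$coefficients) + 1L
  if (n <= k + 1L) stop("AICc undefined: n <= k + 1", call. = FALSE)
  l1 <- model$loglik
  l0 <- null_model$loglik
  r2 <- (1 - exp(-(2 / n) * (l1 - l0))) / (1 - exp((2 / n) * l0))
  aicc <- -2 * l1 + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  bic <- -2 * l1 + k * log(n)
  c(r2 = r2, aicc = aicc, bic = bic)
}

#' Cross-validation scores on held-out data
#'
#' `r2_cv` is the squared Pearson correlation between predicted and
#' measured values; `rmse_cv` is the root mean squared prediction error
#' in response units. Constant measurements leave `r2_cv` undefined
#' (`NA`).
#'
#' @param model fitted `cotton_glm`.
#' @param y measured response on the validation set.
#' @param vi,gdd validation predictors as required by the model's terms.
#' @return named vector `c(r2_cv, rmse_cv)`.
#' @export
cross_validate <- function(model, y, vi = NULL, gdd = NULL) {
  if (!length(y)) stop("empty validation set", call. = FALSE)
  pred <- predict_response(model, vi = vi, gdd = gdd)
  ok <- is.finite(pred) & is.finite(y)
  pred <- pred[ok]; y <- y[ok]
  rmse <- sqrt(mean((pred - y)^2))
  r2 <- if (stats::var(y) == 0 || stats::var(pred) == 0) NA_real_
        else stats::cor(pred, y)^2
  c(r2_cv = r2, rmse_cv = rmse)
}

#' Rank candidate predictor models
#'
#' Orders a score table by cross-validation error: ascending `rmsecv`,
#' ties broken by descending `r2cv`, then ascending `aicc`. Lower RMSEcv
#' with higher R2cv is better model performance.
#'
#' @param scores data frame with columns `predictor`, `r2`, `aicc`,
#'   `bic`, `r2cv`, `rmsecv`.
#' @return the same data frame, reordered, with a `rank` column.
#' @export
rank_models <- function(scores) {
  need <- c("predictor", "r2", "aicc", "bic", "r2cv", "rmsecv")
  miss <- setdiff(need, names(scores))
  if (length(miss)) {
    stop(sprintf("score table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(scores)) stop("empty score table", call. = FALSE)
  ord <- order(scores$rmsecv, -scores$r2cv, scores$aicc)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Screen all candidate predictors for one response
#'
#' For each predictor in `predictors`: remove nothing (outlier handling
#' is the caller's, done once per response on the pooled data), fit the
#' family GLM on the training rows, score against the intercept-only
#' null, cross-validate on the validation rows, and collect one score
#' row. Non-converging or degenerate fits are dropped with a message.
#'
#' @param train,validation data frames holding the response column, a
#'   `gdd` column and one column per candidate predictor.
#' @param response_col response column name.
#' @param family GLM family for this response.
#' @param predictors candidate predictor column names (default
#'   [vi_names()]).
#' @param terms linear-predictor term set (default per family).
#' @return list with the ranked `scores` table and `models` (named list
#'   of fits).
#' @export
screen_predictors <- function(train, validation, response_col,
                              family = c("beta", "gamma", "gaussian"),
                              predictors = vi_names(), terms = NULL) {
  family <- match.arg(family)
  if (is.null(terms)) terms <- glm_terms_default(family)
  y_tr <- train[[response_col]]
  null_terms <- "intercept"
  rows <- list()
  models <- list()
  for (p in predictors) {
    fit <- tryCatch({
      m <- fit_glm(y_tr, vi = train[[p]],
                   gdd = if ("gdd" %in% terms) train$gdd,
                   family = family, terms = terms, predictor_vi = p)
      m0 <- fit_glm(y_tr, vi = train[[p]],
                    gdd = if ("gdd" %in% terms) train$gdd,
                    family = family, terms = null_terms, predictor_vi = p)
      list(m = m, m0 = m0)
    }, error = function(e) {
      message(sprintf("predictor %s skipped: %s", p, conditionMessage(e)))
      NULL
    })
    if (is.null(fit) || !fit$m$converged) {
      if (!is.null(fit)) message(sprintf("predictor %s skipped: no convergence", p))
      next
    }
    ts <- score_train(fit$m, fit$m0)
    cv <- cross_validate(fit$m, validation[[response_col]],
                         vi = validation[[p]],
                         gdd = if ("gdd" %in% terms) validation$gdd)
    rows[[p]] <- data.frame(predictor = p, r2 = ts[["r2"]],
                            aicc = ts[["aicc"]], bic = ts[["bic"]],
                            r2cv = cv[["r2_cv"]], rmsecv = cv[["rmse_cv"]])
    models[[p]] <- fit$m
  }
  if (!length(rows)) stop("no predictor model converged", call. = FALSE)
  scores <- rank_models(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  list(scores = scores, models = models)
}

#' Mechanistic RUE from model outputs
#'
#' Rebuilds the RUE series of each plot from modeled quantities:
#' cumulative IPAR is the IPARf-model prediction times cumulative
#' incident PAR, and biomass is either the biomass-model prediction or
#' the ground measurement (`use_measured_biomass = TRUE`, mirroring the
#' replacement of modeled by measured biomass).
#'
#' @param data per-plot, per-date records ordered by date within plot;
#'   needs columns `plot_id`, `gdd`, `cum_par`, `biomass`, and the
#'   predictor columns the two models use.
#' @param ipar_model fitted beta/logit `cotton_glm` for IPARf.
#' @param biomass_model fitted gamma/log `cotton_glm`; may be `NULL`
#'   when `use_measured_biomass = TRUE`.
#' @param use_measured_biomass use the measured `biomass` column instead
#'   of model predictions.
#' @return `data` with columns `rue_mech` (mechanistic estimate) and
#'   `cum_ipar_pred` added; the first date of each plot has `NA` RUE.
#' @export
mechanistic_rue <- function(data, ipar_model, biomass_model = NULL,
                            use_measured_biomass = FALSE) {
  need <- c("plot_id", "gdd", "cum_par")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  vi_i <- data[[ipar_model$predictor_vi]]
  if (is.null(vi_i)) {
    stop(sprintf("missing predictor column '%s'", ipar_model$predictor_vi),
         call. = FALSE)
  }
  ipar_hat <- predict_response(ipar_model, vi = vi_i, gdd = data$gdd)
  data$cum_ipar_pred <- cumulative_ipar(ipar_hat, data$cum_par)
  if (use_measured_biomass) {
    if (is.null(data$biomass)) stop("missing column 'biomass'", call. = FALSE)
    bm <- data$biomass
  } else {
    if (is.null(biomass_model)) {
      stop("biomass_model required unless use_measured_biomass", call. = FALSE)
    }
    vi_b <- data[[biomass_model$predictor_vi]]
    if (is.null(vi_b)) {
      stop(sprintf("missing predictor column '%s'", biomass_model$predictor_vi),
           call. = FALSE)
    }
    bm <- predict_response(biomass_model, vi = vi_b, gdd = data$gdd)
  }
  data$biomass_used <- bm
  data$rue_mech <- NA_real_
  for (pid in unique(data$plot_id)) {
    rows <- which(data$plot_id == pid)
    if (length(rows) < 2L) {
      stop(sprintf("plot %s has fewer than 2 dates", pid), call. = FALSE)
    }
    data$rue_mech[rows] <- rue_series(bm[rows], data$cum_ipar_pred[rows])
  }
  data
}
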