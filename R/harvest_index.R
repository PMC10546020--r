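#' Predicted harvest index
#'
#' Ratio of the predicted lint yield (kg ha-1) to the highest value of
#' the predicted seasonal biomass trajectory (g m-2, converted with the
#' factor 10). Using the trajectory maximum mirrors the measured-HI
#' definition based on the highest above-ground dry biomass of the
#' season.
#'
#' @param yield_pred_kg_ha predicted lint yield, kg ha-1.
#' @param biomass_pred_g_m2 predicted per-date biomass series, g m-2.
#' @return predicted harvest index (fraction).
#' @export
predict_hi <- function(yield_pred_kg_ha, biomass_pred_g_m2) {
  if (!length(biomass_pred_g_m2)) {
    stop("empty biomass prediction series", call. = FALSE)
  }
  peak <- max(biomass_pred_g_m2)
  if (peak <= 0) {
    stop("degenerate: maximum predicted biomass <= 0", call. = FALSE)
  }
  if (yield_pred_kg_ha < 0) stop("negative predicted yield", call. = FALSE)
  yield_pred_kg_ha / (10 * peak)
}

#' Evaluate predicted against measured harvest index
#'
#' Per group (season by default, plus a pooled row), the squared Pearson
#' correlation and the RMSE between predicted and measured HI. Groups
#' with fewer than 3 plots are skipped with a message.
#'
#' @param estimates data frame with columns `plot_id`, `season`,
#'   `hi_pred`, `hi_meas`.
#' @return data frame with one row per season plus `"pooled"`:
#'   `group`, `n`, `r2`, `rmse`.
#' @export
evaluate_hi <- function(estimates) {
  need <- c("plot_id", "season", "hi_pred", "hi_meas")
  miss <- setdiff(need, names(estimates))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  groups <- c(as.list(split(estimates, estimates$season)),
              list(pooled = estimates))
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) < 3L) {
      message(sprintf("HI group '%s' skipped (n = %d < 3)", g, nrow(d)))
      return(NULL)
    }
    r2 <- if (stats::var(d$hi_meas) == 0 || stats::var(d$hi_pred) == 0)
      NA_real_ else stats::cor(d$hi_pred, d$hi_meas)^2
    data.frame(group = g, n = nrow(d), r2 = r2,
               rmse = sqrt(mean((d$hi_pred - d$hi_meas)^2)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no HI group had >= 3 estimates", call. = FALSE)
  rownames(out) <- NULL
  out
}
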