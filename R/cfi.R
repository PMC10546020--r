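# Open-boll detection in pre-harvest RGB imagery. A simple global
# threshold cannot separate white cotton from bright defoliated
# vegetation and soil, so the image is smoothed with an edge-preserving
# bilateral filter, sharpened with a 5x5 Laplacian, smoothed again with
# a 3x3 arithmetic mean, and only then thresholded at 150 (8-bit scale).

check_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L) {
    stop("expected an h x w x 3 RGB array", call. = FALSE)
  }
  if (any(img < 0 | img > 255)) {
    stop("RGB values must lie on the 8-bit 0-255 scale", call. = FALSE)
  }
  invisible(img)
}

# Reflect-pad a matrix by r pixels on every side.
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc) stop("padding exceeds image size", call. = FALSE)
  ri <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  m[ri, ci, drop = FALSE]
}

# 2D convolution with reflect padding; kernel must be square, odd-sized.
convolve2d_reflect <- function(m, kernel) {
  k <- nrow(kernel)
  if (k != ncol(kernel) || k %% 2L == 0L) {
    stop("kernel must be square with odd size", call. = FALSE)
  }
  r <- (k - 1L) %/% 2L
  p <- pad_reflect(m, r)
  out <- matrix(0, nrow(m), ncol(m))
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      w <- kernel[di, dj]
      if (w == 0) next
      out <- out + w * p[(di - 1L) + seq_len(nrow(m)),
                         (dj - 1L) + seq_len(ncol(m)), drop = FALSE]
    }
  }
  out
}

#' Bilateral filter
#'
#' Edge-preserving smoothing: each output pixel is a normalized average
#' of its neighbourhood with weights that fall off with both spatial
#' distance (`sigma_s`, pixels) and intensity difference (`sigma_r`,
#' 8-bit intensity units). Homogeneous background noise is averaged away
#' while high-contrast boll/background edges, whose intensity gaps far
#' exceed `sigma_r`, are preserved. Reflect padding at borders.
#'
#' @param m numeric matrix (single-channel image).
#' @param sigma_s spatial standard deviation in pixels (default 3).
#' @param sigma_r range standard deviation in intensity units
#'   (default 30).
#' @param radius window radius; defaults to `ceiling(2 * sigma_s)`.
#' @return filtered matrix, same size.
#' @export
bilateral_filter <- function(m, sigma_s = 3, sigma_r = 30, radius = NULL) {
  if (is.null(radius)) radius <- ceiling(2 * sigma_s)
  p <- pad_reflect(m, radius)
  num <- matrix(0, nrow(m), ncol(m))
  den <- matrix(0, nrow(m), ncol(m))
  for (di in -radius:radius) {
    for (dj in -radius:radius) {
      shifted <- p[radius + di + seq_len(nrow(m)),
                   radius + dj + seq_len(ncol(m)), drop = FALSE]
      w_s <- exp(-(di^2 + dj^2) / (2 * sigma_s^2))
      w <- w_s * exp(-(shifted - m)^2 / (2 * sigma_r^2))
      num <- num + w * shifted
      den <- den + w
    }
  }
  num / den
}

#' 5x5 Laplacian sharpening kernel
#'
#' Discrete Laplacian with -1 ring and +24 center; the kernel sums to
#' zero so flat regions are untouched by the additive sharpening step.
#'
#' @return 5x5 numeric matrix.
#' @export
laplacian_kernel5 <- function() {
  k <- matrix(-1, 5L, 5L)
  k[3L, 3L] <- 24
  k
}

#' Pre-harvest image enhancement chain
#'
#' Grayscale (mean of R, G, B) -> bilateral smoothing -> additive 5x5
#' Laplacian sharpening (clipped to 0-255) -> 3x3 arithmetic-mean
#' smoothing. A constant image passes through unchanged. The output is
#' rounded back to the 8-bit scale.
#'
#' @param img `h x w x 3` RGB array on the 0-255 scale, or an already
#'   single-channel matrix.
#' @param sigma_s,sigma_r bilateral parameters, see [bilateral_filter()].
#' @param mean_size side of the arithmetic-mean kernel (default 3).
#' @return single-channel matrix of integers in 0-255.
#' @export
enhance_image <- function(img, sigma_s = 3, sigma_r = 30, mean_size = 3L) {
  if (is.matrix(img)) {
    if (any(img < 0 | img > 255)) {
      stop("image values must lie on the 8-bit 0-255 scale", call. = FALSE)
    }
    gray <- img
  } else {
    check_rgb(img)
    gray <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
  }
  sm <- bilateral_filter(gray, sigma_s = sigma_s, sigma_r = sigma_r)
  sharp <- clamp(sm + convolve2d_reflect(sm, laplacian_kernel5()), 0, 255)
  mk <- matrix(1 / mean_size^2, mean_size, mean_size)
  out <- convolve2d_reflect(sharp, mk)
  round(clamp(out, 0, 255))
}

#' Cotton fiber index of a plot ROI
#'
#' Ratio of white pixels (value strictly greater than the threshold,
#' default 150) to all pixels inside the ROI.
#'
#' @param img single-channel matrix (typically from [enhance_image()];
#'   pass a raw channel to bypass filtering).
#' @param roi polygon vertex matrix in pixel coordinates, or `NULL` for
#'   the whole image.
#' @param threshold white-pixel threshold (default 150, strict `>`).
#' @return one-row data frame: `white_pixels`, `total_pixels`, `cfi`.
#' @export
compute_cfi <- function(img, roi = NULL, threshold = 150) {
  if (!is.matrix(img)) stop("expected a single-channel matrix", call. = FALSE)
  if (is.null(roi)) {
    vals <- img
  } else {
    sel <- roi_pixel_mask(roi, nrow(img), ncol(img))
    if (!any(sel)) stop("empty ROI", call. = FALSE)
    vals <- img[sel]
  }
  white <- sum(vals > threshold)
  total <- length(vals)
  data.frame(white_pixels = white, total_pixels = total, cfi = white / total)
}

#' Linear CFI-to-lint-yield model
#'
#' Ordinary least squares of machine-harvested lint yield on CFI; with
#' one harvest observation per plot there is no train/validation split,
#' so R^2 and RMSE are reported on the fitting data.
#'
#' @param cfi per-plot CFI values.
#' @param yield_kg_ha per-plot lint yield, kg ha-1.
#' @return list of class `cfi_yield_model`: `slope`, `intercept`, `r2`,
#'   `rmse`, `n`.
#' @export
fit_yield_model <- function(cfi, yield_kg_ha) {
  if (length(cfi) != length(yield_kg_ha)) {
    stop("cfi and yield lengths differ", call. = FALSE)
  }
  ok <- is.finite(cfi) & is.finite(yield_kg_ha)
  cfi <- cfi[ok]; yield_kg_ha <- yield_kg_ha[ok]
  if (length(cfi) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(cfi) == 0) {
    stop("degenerate: zero variance in CFI", call. = FALSE)
  }
  fit <- stats::lm(yield_kg_ha ~ cfi)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((yield_kg_ha - mean(yield_kg_ha))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = 1 - rss / tss,
                 rmse = sqrt(rss / length(cfi)),
                 n = length(cfi)),
            class = "cfi_yield_model")
}

#' Predict lint yield from CFI
#'
#' `slope * cfi + intercept`, floored at zero (a negative lint yield is
#' not physical).
#'
#' @param model a [fit_yield_model()] fit.
#' @param cfi CFI values.
#' @return predicted lint yield, kg ha-1.
#' @export
predict_yield <- function(model, cfi) {
  if (!inherits(model, "cfi_yield_model")) {
    stop("not a cfi_yield_model", call. = FALSE)
  }
  pmax(0, model$slope * cfi + model$intercept)
}
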