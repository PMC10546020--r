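#' Multispectral raster constructor
#'
#' Bundles the five reflectance planes (blue, green, red, red-edge,
#' near-infrared) into an `h x w x 5` array with named band slices.
#' Reflectance is unitless on the 0-1 scale; out-of-range values are
#' retained (calibration noise must not silently alter masks) but
#' reported via a warning.
#'
#' @param blue,green,red,rededge,nir numeric matrices of equal dimension.
#' @return array of dimension `c(h, w, 5)`, third dimension named.
#' @export
multispectral_raster <- function(blue, green, red, rededge, nir) {
  bands <- list(blue = blue, green = green, red = red,
                rededge = rededge, nir = nir)
  dims <- lapply(bands, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    stop("all bands must be matrices", call. = FALSE)
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all bands must have the same dimension", call. = FALSE)
  }
  vals <- unlist(bands, use.names = FALSE)
  if (any(!is.finite(vals))) stop("reflectance must be finite", call. = FALSE)
  if (any(vals < 0 | vals > 1)) {
    warning(sprintf("%d reflectance value(s) outside [0, 1] retained",
                    sum(vals < 0 | vals > 1)), call. = FALSE)
  }
  arr <- array(NA_real_, dim = c(dim(blue), 5L),
               dimnames = list(NULL, NULL, names(bands)))
  for (b in names(bands)) arr[, , b] <- bands[[b]]
  arr
}

band_names <- function() c("blue", "green", "red", "rededge", "nir")

check_raster <- function(raster) {
  if (!is.array(raster) || length(dim(raster)) != 3L ||
      dim(raster)[3L] != 5L ||
      !identical(dimnames(raster)[[3L]], band_names())) {
    stop("expected a 5-band raster array (bands blue, green, red, rededge, nir)",
         call. = FALSE)
  }
  invisible(raster)
}

#' Canopy/soil classification index (NDVI x ExG)
#'
#' Per-pixel product of the Normalized Difference Vegetation Index
#' `(NIR - R) / (NIR + R)` and the Excess Greenness index `2G - R - B`,
#' both computed on reflectance. Vegetation scores positive on both
#' factors while bare soil is near zero, so the product separates canopy
#' from background with a single global threshold. Pixels with
#' `NIR + R == 0` map to 0.
#'
#' @param raster a 5-band raster array from [multispectral_raster()].
#' @return numeric matrix of index values, same height/width as input.
#' @export
classification_index <- function(raster) {
  check_raster(raster)
  nir <- raster[, , "nir"]
  r <- raster[, , "red"]
  g <- raster[, , "green"]
  b <- raster[, , "blue"]
  den <- nir + r
  ndvi <- ifelse(den == 0, 0, (nir - r) / den)
  exg <- 2 * g - r - b
  out <- ndvi * exg
  dim(out) <- dim(raster)[1:2]
  out
}

#' Threshold a classification-index plane into a canopy mask
#'
#' Canopy where the index is strictly greater than the threshold
#' (default 0.02), background elsewhere.
#'
#' @param index numeric matrix from [classification_index()].
#' @param threshold global threshold (default 0.02).
#' @return logical matrix; `TRUE` marks canopy.
#' @export
canopy_mask <- function(index, threshold = 0.02) {
  stop_if_not_scalar(threshold, "threshold")
  index > threshold
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Strict interior containment for pixel centers; points on the boundary
#' are treated as outside (the convention used for ROI extraction).
#'
#' @param px,py point coordinates (x rightwards, y downwards, pixel
#'   units: the center of 1-based pixel `(i, j)` is `(j - 0.5, i - 0.5)`).
#' @param poly two-column matrix of polygon vertices (x, y), not
#'   necessarily closed.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- check_polygon(poly)
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

check_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L) stop("polygon must be a 2-column matrix", call. = FALSE)
  # drop an explicit closing vertex
  if (nrow(poly) > 1L && all(poly[1L, ] == poly[nrow(poly), ])) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  area <- polygon_area(poly)
  if (area == 0) stop("polygon has zero area", call. = FALSE)
  poly
}

polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

# Logical matrix of pixels whose centers fall strictly inside the polygon.
roi_pixel_mask <- function(poly, nrow, ncol) {
  cx <- rep(seq_len(ncol) - 0.5, each = nrow)
  cy <- rep(seq_len(nrow) - 0.5, times = ncol)
  matrix(point_in_polygon(cx, cy, poly), nrow = nrow, ncol = ncol)
}

#' Mean canopy reflectance of a plot ROI
#'
#' Averages each band over the pixels whose centers fall inside the ROI
#' polygon and that are canopy in the mask; this is the per-plot,
#' per-date reflectance record the vegetation indices are computed from.
#'
#' @param raster 5-band raster array.
#' @param mask logical canopy mask from [canopy_mask()].
#' @param roi polygon vertex matrix (see [point_in_polygon()]).
#' @param allow_unmasked if `TRUE`, fall back to the unmasked ROI mean
#'   when the ROI contains no canopy pixels instead of erroring.
#' @return one-row data frame: the five band means plus
#'   `n_canopy_pixels`.
#' @export
extract_roi_reflectance <- function(raster, mask, roi, allow_unmasked = FALSE) {
  check_raster(raster)
  if (!identical(dim(mask), dim(raster)[1:2])) {
    stop("mask dimension does not match raster", call. = FALSE)
  }
  inroi <- roi_pixel_mask(roi, nrow(mask), ncol(mask))
  if (!any(inroi)) stop("ROI does not intersect the raster", call. = FALSE)
  sel <- inroi & mask
  if (!any(sel)) {
    if (!allow_unmasked) {
      stop("ROI contains no canopy pixels (set allow_unmasked = TRUE to fall back)",
           call. = FALSE)
    }
    sel <- inroi
  }
  out <- lapply(band_names(), function(b) mean(raster[, , b][sel]))
  names(out) <- band_names()
  out$n_canopy_pixels <- sum(sel)
  as.data.frame(out)
}

#' Parse a WKT POLYGON string
#'
#' Minimal reader for the `POLYGON ((x y, x y, ...))` form used by the
#' ROI table (outer ring only).
#'
#' @param wkt a WKT string.
#' @return two-column vertex matrix.
#' @export
parse_wkt_polygon <- function(wkt) {
  m <- regmatches(wkt, regexpr("\\(\\(.*?\\)\\)", wkt))
  if (!length(m)) stop("not a WKT POLYGON string", call. = FALSE)
  body <- gsub("^\\(\\(|\\)\\)$", "", m)
  parts <- strsplit(trimws(strsplit(body, ",")[[1L]]), "\\s+")
  verts <- t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
  if (anyNA(verts)) stop("unparseable WKT coordinates", call. = FALSE)
  if (nrow(verts) > 1L && all(verts[1L, ] == verts[nrow(verts), ])) {
    verts <- verts[-nrow(verts), , drop = FALSE]   # drop the closing vertex
  }
  colnames(verts) <- c("x", "y")
  verts
}

#' Format a vertex matrix as WKT
#' @param poly two-column vertex matrix.
#' @return WKT `POLYGON ((...))` string (ring closed).
#' @export
format_wkt_polygon <- function(poly) {
  poly <- check_polygon(poly)
  ring <- rbind(poly, poly[1L, ])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%g %g", ring[, 1L], ring[, 2L]), collapse = ", "))
}

#' Read an ROI table (plot_id + WKT polygon)
#' @param path CSV with columns `plot_id`, `wkt`.
#' @return named list of vertex matrices, one per plot.
#' @export
read_roi_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("plot_id", "wkt") %in% names(tab))) {
    stop("ROI table needs columns plot_id, wkt", call. = FALSE)
  }
  rois <- lapply(tab$wkt, parse_wkt_polygon)
  names(rois) <- tab$plot_id
  rois
}
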