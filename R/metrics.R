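# Standalone image statistics: sub-resolution flicker variance and
# Golgi-dispersal convex-hull ratio.

#' Flicker variance of an image patch
#'
#' Quantifies sub-resolution vesicle "flicker": each frame of the patch is
#' normalized to its own mean intensity (removing gain and first-order
#' bleaching), then the temporal variance of every pixel is computed
#' (sample estimator, n - 1), giving a matrix of variances whose mean is
#' the per-cell metric.
#'
#' @param stack an [image_stack()] or 3D array `[y, x, t]`; conventionally
#'   a 50 x 50 px excerpt of 30 frames.
#' @return list of class `flicker_result`: `variance_map` (matrix) and
#'   `mean_variance` (scalar metric).
#' @examples
#' st <- gen_flicker_stack("uniform", shot_noise = FALSE,
#'                         cfg = synth_config(seed = 1))
#' flicker_variance(st)$mean_variance  # exactly 0
#' @export
flicker_variance <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    stop("stack must be a 3D array [y, x, t]", call. = FALSE)
  }
  d <- dim(stack)
  if (d[3L] < 2L) stop("need at least 2 frames", call. = FALSE)
  norm <- array(0, dim = d)
  for (f in seq_len(d[3L])) {
    m <- mean(stack[, , f])
    if (m <= 0) stop(sprintf("frame %d has non-positive mean", f),
                     call. = FALSE)
    norm[, , f] <- stack[, , f] / m
  }
  mu <- apply(norm, c(1L, 2L), mean)
  var_map <- apply(norm, c(1L, 2L), stats::var)
  structure(list(variance_map = var_map, mean_variance = mean(var_map),
                 mean_map = mu),
            class = "flicker_result")
}

#' @export
print.flicker_result <- function(x, ...) {
  cat(sprintf("<flicker_result> %d x %d map, mean variance %.4g\n",
              nrow(x$variance_map), ncol(x$variance_map),
              x$mean_variance))
  invisible(x)
}

#' Threshold a marker image to signal coordinates
#'
#' Helper for dispersal analysis: pixels above the given intensity
#' percentile (computed within the cell mask when supplied) become signal
#' points.
#'
#' @param image numeric matrix.
#' @param percentile intensity percentile threshold (default 95).
#' @param mask optional logical matrix restricting the computation.
#' @return two-column matrix of 0-based `(x, y)` pixel coordinates.
#' @export
threshold_signal_points <- function(image, percentile = 95, mask = NULL) {
  vals <- if (is.null(mask)) image else image[mask]
  thr <- stats::quantile(vals, percentile / 100, names = FALSE)
  sel <- image > thr
  if (!is.null(mask)) sel <- sel & mask
  idx <- which(sel, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
}

#' Golgi dispersal as a convex-hull area fraction
#'
#' The dispersal metric is the area of the convex hull of the
#' trans-Golgi-marker signal coordinates divided by the total cell area.
#' Fewer than 3 non-collinear points yield a dispersal of 0 with a flag
#' (a fully compact Golgi).
#'
#' @param signal_points two-column matrix of `(x, y)` signal coordinates
#'   in pixels.
#' @param cell_mask logical/0-1 matrix of the cell footprint, or a scalar
#'   cell area in px^2.
#' @param pixel_size pixel side in um (default 1: areas in px^2).
#' @return list of class `dispersal_result`: `hull_area`, `cell_area`
#'   (um^2), `dispersal`, `flag`.
#' @export
golgi_dispersal <- function(signal_points, cell_mask, pixel_size = 1) {
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  cell_px2 <- if (is.matrix(cell_mask)) sum(cell_mask != 0) else
    as.numeric(cell_mask)
  if (cell_px2 <= 0) stop("cell mask is empty", call. = FALSE)
  cell_area <- cell_px2 * pixel_size^2
  pts <- unique(signal_points[, 1:2, drop = FALSE])
  degenerate <- nrow(pts) < 3L ||
    polygon_area(pts[grDevices::chull(pts[, 1L], pts[, 2L]), 1L],
                 pts[grDevices::chull(pts[, 1L], pts[, 2L]), 2L]) == 0
  if (degenerate) {
    return(structure(list(hull_area = 0, cell_area = cell_area,
                          dispersal = 0, flag = "degenerate_signal"),
                     class = "dispersal_result"))
  }
  hull <- grDevices::chull(pts[, 1L], pts[, 2L])
  hull_area <- polygon_area(pts[hull, 1L], pts[hull, 2L]) * pixel_size^2
  structure(list(hull_area = hull_area, cell_area = cell_area,
                 dispersal = hull_area / cell_area, flag = NULL),
            class = "dispersal_result")
}

#' @export
print.dispersal_result <- function(x, ...) {
  cat(sprintf("<dispersal_result> hull %.4g / cell %.4g = dispersal %.4g\n",
              x$hull_area, x$cell_area, x$dispersal))
  invisible(x)
}
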