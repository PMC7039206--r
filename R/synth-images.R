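# Synthetic image data: localization-count images of isolated Gaussian
# spots, and flicker stacks (uniform field vs diffusing subresolution
# vesicles).

#' Localization-count image
#'
#' A reconstructed single-molecule localization image: non-negative counts
#' per pixel. Origin is the top-left pixel, x rightward, y downward,
#' 0-based pixel centers.
#'
#' @param pixels numeric matrix (rows = y, columns = x), all `>= 0`.
#' @param pixel_size nm per pixel, `> 0`.
#' @param ground_truth optional list of generator parameters.
#' @return an object of class `localization_image`.
#' @export
localization_image <- function(pixels, pixel_size, ground_truth = NULL) {
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  if (!is.matrix(pixels) || any(pixels < 0) || any(!is.finite(pixels))) {
    stop("pixels must be a finite non-negative matrix", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 ground_truth = ground_truth),
            class = "localization_image")
}

#' @export
print.localization_image <- function(x, ...) {
  cat(sprintf("<localization_image> %d x %d px @ %g nm/px, max %g\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size, max(x$pixels)))
  invisible(x)
}

#' Generate a synthetic localization image of isolated Gaussian spots
#'
#' Places `n_spots` isotropic Gaussian spots at uniformly random sub-pixel
#' positions with pairwise separation of at least `6 * sigma`, each
#' integrating to `counts_per_spot` localizations (pixel values are the
#' Gaussian integrated over each pixel). With `shot_noise = TRUE` each
#' pixel is replaced by a Poisson draw with that mean.
#'
#' @param n_spots number of spots.
#' @param sigma spot standard deviation in nm.
#' @param pixel_size nm per pixel.
#' @param field field of view as `c(width_um, height_um)`.
#' @param counts_per_spot expected localization count per spot.
#' @param shot_noise apply Poisson noise per pixel (default `TRUE`).
#' @param cfg a [synth_config()]; only `seed` is used.
#' @return a [localization_image()] whose ground truth stores the true
#'   centers (px, 0-based), `sigma`, and per-spot drawn counts.
#' @examples
#' img <- gen_localization_image(5, sigma = 24, pixel_size = 16,
#'                               field = c(2, 2), counts_per_spot = 300,
#'                               cfg = synth_config(seed = 4))
#' @export
gen_localization_image <- function(n_spots, sigma = 24, pixel_size = 16,
                                   field = c(10, 10), counts_per_spot = 500,
                                   shot_noise = TRUE,
                                   cfg = synth_config()) {
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  w_px <- round(field[1] * 1000 / pixel_size)
  h_px <- round(field[2] * 1000 / pixel_size)
  sep_px <- 6 * sigma / pixel_size
  margin <- 3 * sigma / pixel_size + 1
  if (w_px - 2 * margin <= 0 || h_px - 2 * margin <= 0) {
    stop("field too small for the requested spot size", call. = FALSE)
  }
  with_seed(cfg$seed, {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n_spots) {
      px <- runif(1, margin, w_px - 1 - margin)
      py <- runif(1, margin, h_px - 1 - margin)
      if (!length(xs) || all((xs - px)^2 + (ys - py)^2 >= sep_px^2)) {
        xs <- c(xs, px); ys <- c(ys, py)
      }
      tries <- tries + 1L
      if (tries > 200L * max(1L, n_spots)) {
        stop("field too small for the requested spot separation",
             call. = FALSE)
      }
    }
    img <- matrix(0, nrow = h_px, ncol = w_px)
    s_px <- sigma / pixel_size
    for (i in seq_len(n_spots)) {
      x0 <- floor(xs[i] - 4 * s_px); x1 <- ceiling(xs[i] + 4 * s_px)
      y0 <- floor(ys[i] - 4 * s_px); y1 <- ceiling(ys[i] + 4 * s_px)
      xi <- max(0, x0):min(w_px - 1, x1)
      yi <- max(0, y0):min(h_px - 1, y1)
      # integral of the Gaussian over each pixel (0-based pixel centers)
      fx <- pnorm(xi + 0.5, xs[i], s_px) - pnorm(xi - 0.5, xs[i], s_px)
      fy <- pnorm(yi + 0.5, ys[i], s_px) - pnorm(yi - 0.5, ys[i], s_px)
      img[yi + 1, xi + 1] <- img[yi + 1, xi + 1] +
        counts_per_spot * outer(fy, fx)
    }
    if (shot_noise) {
      img[] <- rpois(length(img), lambda = img)
    }
    localization_image(
      img, pixel_size,
      ground_truth = list(x_px = xs, y_px = ys, sigma_nm = sigma,
                          sigma_px = s_px, counts_per_spot = counts_per_spot,
                          n_spots = n_spots, shot_noise = shot_noise,
                          total_counts = sum(img), seed = cfg$seed))
  })
}

#' Spot count for a target density
#'
#' Converts a spot density expressed per 10 square microns into the number
#' of spots to place over a field of given area.
#'
#' @param density_per_10um2 spots per 10 um^2.
#' @param area_um2 field area in um^2.
#' @return integer spot count (rounded).
#' @export
spots_for_density <- function(density_per_10um2, area_um2) {
  as.integer(round(density_per_10um2 * area_um2 / 10))
}

#' Image stack
#'
#' A simple container for a time-lapse: a 3D array indexed `[y, x, frame]`.
#'
#' @param frames 3D numeric array `[y, x, t]`.
#' @param frame_interval seconds per frame (metadata only).
#' @param ground_truth optional generator parameters.
#' @return an object of class `image_stack` (the array, with attributes).
#' @export
image_stack <- function(frames, frame_interval = NA_real_,
                        ground_truth = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("frames must be a 3D array [y, x, t]", call. = FALSE)
  }
  structure(frames, frame_interval = frame_interval,
            ground_truth = ground_truth, class = "image_stack")
}

#' Generate a synthetic flicker stack
#'
#' Emulates the live-cell patches used to quantify sub-resolution vesicle
#' "flicker". `"uniform"` gives a spatially constant field (a freely
#' diffusing cytosolic fluorophore); `"vesicles"` adds diffusing
#' sub-resolution Gaussian spots, with the background lowered so both modes
#' share the same expected mean intensity. Shot noise is Poisson per pixel.
#'
#' @param mode `"uniform"` or `"vesicles"`.
#' @param n_frames frames in the stack (default 30).
#' @param patch patch side in pixels (default 50).
#' @param vesicle_density spots per um^2 in `"vesicles"` mode.
#' @param mean_intensity expected mean counts per pixel (both modes).
#' @param pixel_size_um pixel size in um (sets how many vesicles fit).
#' @param sigma_px spot sigma in pixels (sub-resolution: ~1 px).
#' @param step_px diffusion step SD per frame, pixels.
#' @param shot_noise apply Poisson noise (default `TRUE`).
#' @param cfg a [synth_config()]; only `seed` is used.
#' @return an [image_stack()] with ground truth.
#' @export
gen_flicker_stack <- function(mode = c("uniform", "vesicles"),
                              n_frames = 30L, patch = 50L,
                              vesicle_density = 2.7, mean_intensity = 100,
                              pixel_size_um = 0.1, sigma_px = 1.2,
                              step_px = 1.5, shot_noise = TRUE,
                              cfg = synth_config()) {
  mode <- match.arg(mode)
  if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  with_seed(cfg$seed, {
    stack <- array(0, dim = c(patch, patch, n_frames))
    gt <- list(mode = mode, mean_intensity = mean_intensity,
               shot_noise = shot_noise, seed = cfg$seed)
    if (mode == "uniform") {
      stack[] <- mean_intensity
    } else {
      area_um2 <- (patch * pixel_size_um)^2
      n_ves <- max(1L, round(vesicle_density * area_um2))
      amp_total <- 0.6 * mean_intensity * patch^2  # 60% of signal in spots
      amp <- amp_total / n_ves                     # counts per spot
      bg <- mean_intensity - amp_total / patch^2
      if (bg < 0) stop("mean_intensity too low for spot load", call. = FALSE)
      xs <- runif(n_ves, 0, patch - 1)
      ys <- runif(n_ves, 0, patch - 1)
      px <- seq(0, patch - 1)
      for (f in seq_len(n_frames)) {
        frame <- matrix(bg, patch, patch)
        for (i in seq_len(n_ves)) {
          fx <- pnorm(px + 0.5, xs[i], sigma_px) -
            pnorm(px - 0.5, xs[i], sigma_px)
          fy <- pnorm(px + 0.5, ys[i], sigma_px) -
            pnorm(px - 0.5, ys[i], sigma_px)
          frame <- frame + amp * outer(fy, fx)
        }
        stack[, , f] <- frame
        # reflecting random walk keeps spots (and the mean) in the patch
        xs <- abs(xs + rnorm(n_ves, 0, step_px))
        ys <- abs(ys + rnorm(n_ves, 0, step_px))
        xs <- patch - 1 - abs(patch - 1 - xs)
        ys <- patch - 1 - abs(patch - 1 - ys)
      }
      gt$n_vesicles <- n_ves
      gt$amp <- amp
      gt$background <- bg
    }
    if (shot_noise) {
      stack[] <- rpois(length(stack), lambda = stack)
    }
    image_stack(stack, ground_truth = gt)
  })
}
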