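#' Segmented EM scene of closed contours
#'
#' Holds the manual segmentation of one electron micrograph: labeled
#' objects (mitochondrion, vesicle, other), each a list of closed contours
#' of `(x, y, z)` points in pixels, plus the pixel scale. Coordinates stay
#' in pixels until morphometry converts them to nm.
#'
#' @param objects list of objects; each is a list with `label` (one of
#'   `"mitochondrion"`, `"vesicle"`, `"other"`) and `contours`, a list of
#'   numeric matrices with columns `x`, `y`, `z` (constant z: one section
#'   per contour). Morphometry requires >= 3 points per contour; the
#'   container itself accepts degenerate contours so that partially drawn
#'   segmentation files still parse.
#' @param scale nm per pixel, `> 0`.
#' @param source file path or `"synthetic"`.
#' @param ground_truth optional list of true generator parameters.
#' @return an object of class `contour_scene`.
#' @export
contour_scene <- function(objects, scale, source = "synthetic",
                          ground_truth = NULL) {
  stopifnot_scalar(scale, "scale", positive = TRUE)
  ok_labels <- c("mitochondrion", "vesicle", "other")
  for (i in seq_along(objects)) {
    ob <- objects[[i]]
    if (is.null(ob$label) || !ob$label %in% ok_labels) {
      stop(sprintf("object %d has no valid label", i), call. = FALSE)
    }
    for (j in seq_along(ob$contours)) {
      ct <- ob$contours[[j]]
      if (!is.matrix(ct) || ncol(ct) != 3L) {
        stop(sprintf("object %d contour %d is not an (x, y, z) matrix",
                     i, j), call. = FALSE)
      }
      if (nrow(ct) < 1L) {
        stop(sprintf("object %d contour %d is empty", i, j), call. = FALSE)
      }
      if (length(unique(ct[, 3L])) != 1L) {
        stop(sprintf("object %d contour %d spans multiple z sections", i, j),
             call. = FALSE)
      }
    }
  }
  structure(list(objects = objects, scale = scale, source = source,
                 ground_truth = ground_truth),
            class = "contour_scene")
}

#' @export
print.contour_scene <- function(x, ...) {
  labs <- vapply(x$objects, `[[`, character(1), "label")
  ncont <- vapply(x$objects, function(o) length(o$contours), integer(1))
  cat(sprintf("<contour_scene> %s; scale %g nm/px; source %s\n",
              paste(sprintf("%s x%d", labs, ncont), collapse = ", "),
              x$scale, x$source))
  invisible(x)
}

# All contours carrying a given label, as a flat list of matrices.
scene_contours <- function(scene, label) {
  out <- list()
  for (ob in scene$objects) {
    if (ob$label == label) out <- c(out, ob$contours)
  }
  out
}

# Minimum distance from points (px, py) to a closed polyline (vx, vy).
dist_to_polyline <- function(px, py, vx, vy) {
  n <- length(vx)
  x1 <- vx; y1 <- vy
  x2 <- vx[c(2:n, 1L)]; y2 <- vy[c(2:n, 1L)]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-300
  res <- numeric(length(px))
  for (k in seq_along(px)) {
    t <- pmin(1, pmax(0, ((px[k] - x1) * dx + (py[k] - y1) * dy) / len2))
    qx <- x1 + t * dx; qy <- y1 + t * dy
    res[k] <- sqrt(min((px[k] - qx)^2 + (py[k] - qy)^2))
  }
  res
}

#' Generate a synthetic vesicle-capture EM scene
#'
#' Draws one irregular mitochondrial profile and `n_vesicles` small
#' polygonal vesicles around it, mimicking a thin-section micrograph taken
#' after vesicle capture at mitochondria. A fraction `capture_fraction` of
#' vesicles is placed with its boundary within 15 nm of the mitochondrial
#' contour ("captured"); the remainder is kept at least 100 nm away.
#' Vesicle diameters are Normal(`diameter_mean`, `diameter_sd`) truncated
#' below at `2 * scale` (one pixel radius).
#'
#' @param n_vesicles number of vesicles, `>= 0`.
#' @param diameter_mean,diameter_sd diameter distribution in nm.
#' @param mito_shape list parameterizing the mitochondrial outline:
#'   `r_nm` mean radius, `aspect` x-elongation, `wobble` relative radial
#'   modulation, `n_points` vertices.
#' @param capture_fraction fraction of vesicles captured, in `[0, 1]`.
#' @param scale nm per pixel, `> 0`.
#' @param n_vertices vertices per vesicle polygon (minimum 16, so the
#'   polar-radius average is well conditioned).
#' @param cfg a [synth_config()]; only `seed` is used.
#' @return a [contour_scene()] whose `ground_truth` holds per-vesicle true
#'   centers (nm), diameters (nm) and capture flags.
#' @examples
#' sc <- gen_em_scene(20, 30, 9.4, capture_fraction = 0.5, scale = 1,
#'                    cfg = synth_config(seed = 3))
#' @export
gen_em_scene <- function(n_vesicles, diameter_mean = 30, diameter_sd = 9.4,
                         mito_shape = list(r_nm = 400, aspect = 1.6,
                                           wobble = 0.08, n_points = 240),
                         capture_fraction = 1, scale = 1, n_vertices = 32L,
                         cfg = synth_config()) {
  stopifnot_scalar(diameter_mean, "diameter_mean", positive = TRUE)
  stopifnot_scalar(scale, "scale", positive = TRUE)
  if (capture_fraction < 0 || capture_fraction > 1) {
    stop("capture_fraction must lie in [0, 1]", call. = FALSE)
  }
  n_vertices <- max(16L, as.integer(n_vertices))
  with_seed(cfg$seed, {
    shp <- utils::modifyList(
      list(r_nm = 400, aspect = 1.6, wobble = 0.08, n_points = 240),
      mito_shape)
    theta <- seq(0, 2 * pi, length.out = shp$n_points + 1L)[-(shp$n_points + 1L)]
    phase <- runif(2, 0, 2 * pi)
    r <- shp$r_nm * (1 + shp$wobble * sin(3 * theta + phase[1]) +
                       0.5 * shp$wobble * sin(2 * theta + phase[2]))
    mx <- shp$aspect * r * cos(theta)  # nm, centered at origin
    my <- r * sin(theta)

    n_cap <- round(n_vesicles * capture_fraction)
    captured <- c(rep(TRUE, n_cap), rep(FALSE, n_vesicles - n_cap))
    diam <- numeric(n_vesicles)
    cx <- numeric(n_vesicles)
    cy <- numeric(n_vesicles)
    # outward normals at each mito vertex (scene is star-shaped about 0)
    seg_prev <- c(shp$n_points, seq_len(shp$n_points - 1L))
    seg_next <- c(2:shp$n_points, 1L)
    tx <- mx[seg_next] - mx[seg_prev]
    ty <- my[seg_next] - my[seg_prev]
    nl <- sqrt(tx^2 + ty^2)
    nx <- ty / nl
    ny <- -tx / nl
    flip <- (nx * mx + ny * my) < 0
    nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]

    halo <- max(shp$r_nm * shp$aspect, shp$r_nm) + 600
    for (i in seq_len(n_vesicles)) {
      d <- max(2 * scale, rnorm(1, diameter_mean, diameter_sd))
      placed <- FALSE
      for (try in seq_len(400L)) {
        if (captured[i]) {
          k <- sample.int(shp$n_points, 1L)
          gap <- runif(1, 0.5, 12)  # boundary-to-contour distance target, nm
          px <- mx[k] + nx[k] * (d / 2 + gap)
          py <- my[k] + ny[k] * (d / 2 + gap)
          dmin <- dist_to_polyline(px, py, mx, my)
          if (dmin < d / 2 + 0.25 || dmin > d / 2 + 14.5) next
        } else {
          px <- runif(1, min(mx) - halo, max(mx) + halo)
          py <- runif(1, min(my) - halo, max(my) + halo)
          if (point_in_polygon(px, py, mx, my)) next
          dmin <- dist_to_polyline(px, py, mx, my)
          if (dmin < 100 + d / 2) next
        }
        ok <- TRUE
        if (i > 1L) {
          prev <- seq_len(i - 1L)
          if (any(sqrt((cx[prev] - px)^2 + (cy[prev] - py)^2) <
                    (diam[prev] + d) / 2 + 2)) ok <- FALSE
        }
        if (ok) {
          cx[i] <- px; cy[i] <- py; diam[i] <- d
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf(
          "vesicle placement failed after bounded retries (seed %d)",
          cfg$seed), call. = FALSE)
      }
    }

    ves_contours <- lapply(seq_len(n_vesicles), function(i) {
      ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)] +
        runif(1, 0, 2 * pi / n_vertices)
      cbind(x = (cx[i] + diam[i] / 2 * cos(ang)) / scale,
            y = (cy[i] + diam[i] / 2 * sin(ang)) / scale,
            z = 0)
    })
    objects <- list(list(label = "mitochondrion",
                         contours = list(cbind(x = mx / scale, y = my / scale,
                                               z = 0))))
    if (n_vesicles > 0L) {
      objects <- c(objects, list(list(label = "vesicle",
                                      contours = ves_contours)))
    }
    contour_scene(
      objects, scale = scale, source = "synthetic",
      ground_truth = list(
        vesicles = data.frame(
          vesicle_id = seq_len(n_vesicles),
          cx_nm = cx[seq_len(n_vesicles)], cy_nm = cy[seq_len(n_vesicles)],
          diameter_nm = diam[seq_len(n_vesicles)],
          captured = captured[seq_len(n_vesicles)]),
        mito = list(shape = shp, phase = phase),
        capture_fraction = capture_fraction,
        diameter_mean = diameter_mean, diameter_sd = diameter_sd,
        scale = scale, seed = cfg$seed)
    )
  })
}
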