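# Spot detection and sizing in localization images: topographic-prominence
# maxima, 2D Gaussian window fits, FWHM summaries and spot densities.

#' Find local maxima by topographic prominence
#'
#' A local maximum is retained when its prominence — peak value minus the
#' highest saddle connecting it to any higher peak — exceeds `prominence`.
#' The image border is treated as -Inf (peaks cannot connect through the
#' outside), so the global maximum has infinite prominence. Plateau maxima
#' report the centroid pixel of the plateau. Implemented by a single
#' union-find sweep over pixels in decreasing intensity order.
#'
#' @param image a [localization_image()] or numeric matrix.
#' @param prominence threshold (strictly greater retains the peak);
#'   default 5.
#' @return data.frame with 0-based integer `x`, `y`, the peak `value`, and
#'   `prominence` (`Inf` for peaks with no higher neighbor peak).
#' @export
find_spot_maxima <- function(image, prominence = 5) {
  stopifnot_scalar(prominence, "prominence", positive = TRUE)
  v <- if (inherits(image, "localization_image")) image$pixels else image
  h <- nrow(v); w <- ncol(v)
  n <- h * w
  if (n == 0L || max(v) == min(v)) {
    return(data.frame(x = integer(0), y = integer(0),
                      value = numeric(0), prominence = numeric(0)))
  }
  ord <- order(v, -seq_len(n), decreasing = TRUE)  # value desc, index asc
  rank_of <- integer(n)
  rank_of[ord] <- seq_len(n)
  parent <- integer(n)          # 0 = not yet activated
  comp_peak_val <- numeric(n)   # per root
  comp_peak_px <- integer(n)
  prom <- rep(NA_real_, n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  row_of <- ((seq_len(n) - 1L) %% h) + 1L
  col_of <- ((seq_len(n) - 1L) %/% h) + 1L
  for (px in ord) {
    r <- row_of[px]; cc <- col_of[px]
    parent[px] <- px
    comp_peak_val[px] <- v[px]
    comp_peak_px[px] <- px
    roots <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; ccc <- cc + dc
      if (rr < 1L || rr > h || ccc < 1L || ccc > w) next
      nb <- (ccc - 1L) * h + rr
      if (parent[nb] != 0L) roots <- c(roots, find_root(nb))
    }
    roots <- unique(c(roots, px))
    if (length(roots) > 1L) {
      # winner: highest peak; ties broken by earlier activation
      peak_vals <- comp_peak_val[roots]
      win <- roots[order(-peak_vals, rank_of[comp_peak_px[roots]])][1L]
      for (rt in roots) {
        if (rt == win) next
        # the merge level v[px] is the saddle for the losing peak
        if (is.na(prom[comp_peak_px[rt]]) && comp_peak_px[rt] != px) {
          prom[comp_peak_px[rt]] <- comp_peak_val[rt] - v[px]
        }
        parent[rt] <- win
      }
      comp_peak_val[win] <- max(peak_vals)
    }
  }
  roots <- unique(vapply(which(parent > 0L), find_root, integer(1)))
  for (rt in roots) prom[comp_peak_px[rt]] <- Inf
  keep <- which(!is.na(prom) & prom > prominence)
  if (!length(keep)) {
    return(data.frame(x = integer(0), y = integer(0),
                      value = numeric(0), prominence = numeric(0)))
  }
  # plateau centroid: connected equal-valued region around each peak
  res <- lapply(keep, function(px) {
    val <- v[px]
    seen <- px
    frontier <- px
    while (length(frontier)) {
      nxt <- integer(0)
      for (q in frontier) {
        r <- row_of[q]; cc <- col_of[q]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; ccc <- cc + dc
          if (rr < 1L || rr > h || ccc < 1L || ccc > w) next
          nb <- (ccc - 1L) * h + rr
          if (v[nb] == val && !(nb %in% seen)) {
            seen <- c(seen, nb)
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
    }
    c(x = round(mean(col_of[seen])) - 1L, y = round(mean(row_of[seen])) - 1L,
      value = val, prominence = prom[px])
  })
  out <- as.data.frame(do.call(rbind, res))
  out <- out[!duplicated(out[, c("x", "y")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a 2D Gaussian to a spot window
#'
#' Least-squares fit of `f(x, y) = z0 + A * exp(-((x - x0)^2 / (2 sx^2) +
#' (y - y0)^2 / (2 sy^2)))` over a `window x window` pixel region centered
#' on the detected coordinate. The FWHM is `2 * sqrt(2 ln 2) * sy *
#' pixel_size` (the y-axis sigma, matching the original analysis). Windows
#' clipped at the image border are fitted anyway and flagged. Fits whose
#' sigma exceeds half the window, collapses toward zero, or that fail to
#' converge are marked `converged = FALSE` and excluded from summaries.
#'
#' @param image a [localization_image()].
#' @param center integer `c(x, y)` 0-based pixel coordinate.
#' @param window odd window side in pixels (default 41).
#' @return list of class `spot_fit`: `x0`, `y0` (0-based px, full-image
#'   frame), `sigma_x`, `sigma_y` (px), `A`, `z0`, `fwhm` (nm),
#'   `converged`, `clipped`.
#' @export
fit_spot <- function(image, center, window = 41L) {
  stopifnot(inherits(image, "localization_image"))
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  v <- image$pixels
  h <- nrow(v); w <- ncol(v)
  half <- (window - 1L) %/% 2L
  cx <- center[1L]; cy <- center[2L]
  x_lo <- max(0L, cx - half); x_hi <- min(w - 1L, cx + half)
  y_lo <- max(0L, cy - half); y_hi <- min(h - 1L, cy + half)
  clipped <- (x_hi - x_lo + 1L) < window || (y_hi - y_lo + 1L) < window
  xs <- x_lo:x_hi
  ys <- y_lo:y_hi
  sub <- v[ys + 1L, xs + 1L, drop = FALSE]
  df <- data.frame(x = rep(xs, each = length(ys)),
                   y = rep(ys, times = length(xs)),
                   z = as.vector(sub))
  z0_init <- min(df$z)
  a_init <- max(df$z) - z0_init
  out <- structure(list(x0 = NA_real_, y0 = NA_real_, sigma_x = NA_real_,
                        sigma_y = NA_real_, A = NA_real_, z0 = NA_real_,
                        fwhm = NA_real_, converged = FALSE,
                        clipped = clipped),
                   class = "spot_fit")
  if (a_init <= 0) return(out)
  fit <- NULL
  for (s_init in c(1.5, 3, 0.8)) {
    fit <- tryCatch(
      stats::nls(z ~ z0 + A * exp(-((x - x0)^2 / (2 * sx^2) +
                                      (y - y0)^2 / (2 * sy^2))),
                 data = df,
                 start = list(z0 = z0_init, A = a_init, x0 = cx, y0 = cy,
                              sx = s_init, sy = s_init),
                 algorithm = "port",
                 lower = c(z0 = -Inf, A = 0, x0 = x_lo, y0 = y_lo,
                           sx = 1e-3, sy = 1e-3),
                 upper = c(z0 = Inf, A = Inf, x0 = x_hi, y0 = y_hi,
                           sx = window, sy = window),
                 control = stats::nls.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(out)
  p <- as.list(stats::coef(fit))
  out$x0 <- p$x0; out$y0 <- p$y0
  out$sigma_x <- p$sx; out$sigma_y <- p$sy
  out$A <- p$A; out$z0 <- p$z0
  # sigma below ~0.2 px is unidentifiable from pixel-center samples (the
  # spot is a delta); sigma above window/2 means the fit absorbed the
  # background
  ok <- p$sx > 0.2 && p$sy > 0.2 && p$sx <= window / 2 &&
    p$sy <= window / 2 && p$A > 0
  if (ok) {
    out$converged <- TRUE
    out$fwhm <- 2 * sqrt(2 * log(2)) * p$sy * image$pixel_size
  }
  out
}

#' Summarize spot fits for one cell
#'
#' @param fits list of `spot_fit` objects.
#' @param cell_area cell footprint in um^2 (user-supplied mask or field
#'   area).
#' @param breaks histogram breaks for FWHM in nm (passed to [hist()]).
#' @return list of class `spot_summary`: `n_spots`, `n_converged`,
#'   `mean_fwhm`, `median_fwhm` (nm), `density_per_10um2`, `histogram`,
#'   and the per-spot `table`. Empty summaries are flagged.
#' @export
spot_summary <- function(fits, cell_area, breaks = "Sturges") {
  stopifnot_scalar(cell_area, "cell_area", positive = TRUE)
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(x0 = f$x0, y0 = f$y0, sigma_x = f$sigma_x,
               sigma_y = f$sigma_y, A = f$A, z0 = f$z0, fwhm = f$fwhm,
               converged = f$converged, clipped = f$clipped)
  }))
  conv <- tab[!is.na(tab$converged) & tab$converged, , drop = FALSE]
  if (!nrow(conv)) {
    return(structure(list(n_spots = length(fits), n_converged = 0L,
                          mean_fwhm = NA_real_, median_fwhm = NA_real_,
                          density_per_10um2 = 0, histogram = NULL,
                          table = tab, flag = "no_converged_fits"),
                     class = "spot_summary"))
  }
  structure(list(
    n_spots = length(fits), n_converged = nrow(conv),
    mean_fwhm = mean(conv$fwhm), median_fwhm = stats::median(conv$fwhm),
    density_per_10um2 = nrow(conv) / cell_area * 10,
    histogram = graphics::hist(conv$fwhm, breaks = breaks, plot = FALSE),
    table = tab, flag = NULL), class = "spot_summary")
}

#' @export
print.spot_summary <- function(x, ...) {
  cat(sprintf(
    "<spot_summary> %d/%d converged; FWHM mean %.1f nm, median %.1f nm; %.1f spots per 10 um^2\n",
    x$n_converged, x$n_spots, x$mean_fwhm, x$median_fwhm,
    x$density_per_10um2))
  invisible(x)
}

#' Detect, fit and summarize all spots in a localization image
#'
#' @param image a [localization_image()].
#' @param prominence detection threshold (default 5).
#' @param window fit window in px (default 41).
#' @param cell_area cell footprint in um^2; defaults to the full field.
#' @return a `spot_summary`.
#' @export
storm_analyze <- function(image, prominence = 5, window = 41L,
                          cell_area = NULL) {
  if (is.null(cell_area)) {
    cell_area <- prod(dim(image$pixels)) * (image$pixel_size / 1000)^2
  }
  peaks <- find_spot_maxima(image, prominence)
  fits <- lapply(seq_len(nrow(peaks)), function(i) {
    fit_spot(image, c(peaks$x[i], peaks$y[i]), window)
  })
  spot_summary(fits, cell_area)
}
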