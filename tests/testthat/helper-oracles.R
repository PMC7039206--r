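# Independent oracles used across the suite. Deliberately brute-force and
# implementation-independent of the package's primary code paths.

# Exhaustive topographic prominence: for each candidate local maximum,
# descend through the distinct image levels and flood-fill the superlevel
# set containing the peak until it touches strictly higher terrain; the
# first (highest) such level is the key saddle.
prominence_bruteforce <- function(v) {
  h <- nrow(v); w <- ncol(v)
  is_max <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w) nb <- c(nb, v[rr, c2])
    }
    is_max[r, cc] <- all(v[r, cc] >= nb)
  }
  flood <- function(r0, c0, level) {
    seen <- matrix(FALSE, h, w)
    stack_r <- r0; stack_c <- c0
    seen[r0, c0] <- TRUE
    while (length(stack_r)) {
      r <- stack_r[1]; cc <- stack_c[1]
      stack_r <- stack_r[-1]; stack_c <- stack_c[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1 || rr > h || c2 < 1 || c2 > w) next
        if (!seen[rr, c2] && v[rr, c2] >= level) {
          seen[rr, c2] <- TRUE
          stack_r <- c(stack_r, rr); stack_c <- c(stack_c, c2)
        }
      }
    }
    seen
  }
  out <- data.frame(r = integer(0), c = integer(0), value = numeric(0),
                    prominence = numeric(0))
  idx <- which(is_max, arr.ind = TRUE)
  levels <- sort(unique(as.vector(v)), decreasing = TRUE)
  for (i in seq_len(nrow(idx))) {
    r0 <- idx[i, 1]; c0 <- idx[i, 2]
    peak <- v[r0, c0]
    prom <- Inf
    for (L in levels[levels <= peak]) {
      comp <- flood(r0, c0, L)
      if (max(v[comp]) > peak) {
        prom <- peak - L
        break
      }
    }
    out <- rbind(out, data.frame(r = r0, c = c0, value = peak,
                                 prominence = prom))
  }
  out
}

# Brute-force convex hull area for small point sets: a point is a hull
# vertex iff it is not strictly inside the hull of the others, detected by
# checking it lies inside no triangle of other points; vertices are then
# ordered by angle about the centroid and the shoelace applied.
hull_area_bruteforce <- function(pts) {
  n <- nrow(pts)
  stopifnot(n <= 12)
  in_triangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 > 0 && s2 > 0 && s3 > 0) || (s1 < 0 && s2 < 0 && s3 < 0)
  }
  vertex <- rep(TRUE, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    combs <- utils::combn(others, 3)
    for (k in seq_len(ncol(combs))) {
      if (in_triangle(pts[i, ], pts[combs[1, k], ], pts[combs[2, k], ],
                      pts[combs[3, k], ])) {
        vertex[i] <- FALSE
        break
      }
    }
  }
  hp <- pts[vertex, , drop = FALSE]
  cen <- colMeans(hp)
  o <- order(atan2(hp[, 2] - cen[2], hp[, 1] - cen[1]))
  hp <- hp[o, , drop = FALSE]
  m <- nrow(hp)
  j <- c(m, seq_len(m - 1))
  abs(sum(hp[j, 1] * hp[, 2] - hp[, 1] * hp[j, 2])) / 2
}

# Closed-form transport half-times implied by the RUSH generator's ground
# truth (logistic midpoint; the declining line's crossing of it).
rush_truth_halftimes <- function(gt) {
  half <- (gt$y0 + gt$ymax) / 2
  y_peak <- gt$y0 + (gt$ymax - gt$y0) / (1 + (gt$x_half / gt$t_peak)^gt$n)
  t_pm <- gt$t_peak + (half - y_peak) / gt$decay_slope
  list(t_er_golgi = gt$x_half, t_er_pm = t_pm,
       transit = t_pm - gt$x_half)
}

# Spot image sampled at pixel centers from the fit model itself, for
# exact-recovery tests of the spot fitter.
gaussian_spot_image <- function(h, w, x0, y0, sx, sy, A, z0, pixel_size) {
  xs <- 0:(w - 1)
  ys <- 0:(h - 1)
  img <- z0 + A * outer(exp(-(ys - y0)^2 / (2 * sy^2)),
                        exp(-(xs - x0)^2 / (2 * sx^2)))
  localization_image(img, pixel_size)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
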