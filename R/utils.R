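# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their own seed and never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic 31-bit sub-seed from a parent seed and a stream index.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 65537) %% 2147483629
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("%s must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("%s must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("%s must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

# Union of closed intervals given as a 2-column matrix [lo, hi]; returns a
# matrix of disjoint intervals sorted by lo. Empty input -> 0-row matrix.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  keep <- iv[, 2L] > iv[, 1L]
  iv <- iv[keep, , drop = FALSE]
  if (nrow(iv) == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  o <- order(iv[, 1L])
  iv <- iv[o, , drop = FALSE]
  lo <- iv[1L, 1L]
  hi <- iv[1L, 2L]
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv[i, 1L] <= hi) {
      hi <- max(hi, iv[i, 2L])
    } else {
      out <- rbind(out, c(lo, hi))
      lo <- iv[i, 1L]
      hi <- iv[i, 2L]
    }
  }
  rbind(out, c(lo, hi))
}

# Shoelace area of a polygon given x, y vertex vectors (open ring).
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Even-odd point-in-polygon test (ray casting), vectorized over points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
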