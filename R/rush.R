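# RUSH secretory-transport kinetics: Golgi fraction, logistic fit of the
# rise, line fit of the decline, and the three transport half-times.

#' Golgi fluorescence fraction per frame
#'
#' Converts per-frame integrated densities of a Golgi ROI and a whole-cell
#' ROI into the fraction of cargo fluorescence at the Golgi. Small negative
#' ratios (background subtraction artifacts) are clipped to 0 with a
#' warning; values are capped at 1.
#'
#' @param golgi_integrated numeric vector of Golgi integrated density per
#'   frame (a.u. * px).
#' @param cell_integrated numeric vector of whole-cell integrated density,
#'   same length, all `> 0`.
#' @param times frame time points (minutes); defaults to 0-based frame
#'   index.
#' @param meta metadata list passed to [timed_trace()].
#' @return a [timed_trace()] of fractions in `[0, 1]`, unit minutes.
#' @export
golgi_fraction <- function(golgi_integrated, cell_integrated,
                           times = seq_along(golgi_integrated) - 1,
                           meta = list()) {
  if (length(golgi_integrated) != length(cell_integrated)) {
    stop("golgi and cell series must have equal length", call. = FALSE)
  }
  bad <- which(cell_integrated <= 0)
  if (length(bad)) {
    stop(sprintf("cell integrated density is <= 0 at frame %d", bad[1L]),
         call. = FALSE)
  }
  frac <- golgi_integrated / cell_integrated
  if (any(frac < 0)) {
    warning(sprintf("clipped %d negative fraction(s) to 0", sum(frac < 0)),
            call. = FALSE)
    frac[frac < 0] <- 0
  }
  frac[frac > 1] <- 1
  timed_trace(times, frac, unit = "min", meta = meta)
}

new_rush_fit <- function() {
  structure(list(y0 = NA_real_, ymax = NA_real_, x_half = NA_real_,
                 n = NA_real_, a = NA_real_, b = NA_real_,
                 t_half_er_golgi = NA_real_, t_half_er_pm = NA_real_,
                 golgi_transit = NA_real_,
                 fit_diagnostics = list(rss = NA_real_, converged = FALSE,
                                        flags = character(0))),
            class = "rush_fit")
}

#' @export
print.rush_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<rush_fit> y0=%.4g ymax=%.4g x_half=%.4g n=%.3g | ",
           "a=%.4g b=%.4g\n  t1/2 ER->Golgi=%.4g  ER->PM=%.4g  ",
           "transit=%.4g min%s\n"),
    x$y0, x$ymax, x$x_half, x$n, x$a, x$b,
    x$t_half_er_golgi, x$t_half_er_pm, x$golgi_transit,
    if (length(x$fit_diagnostics$flags)) {
      paste0("  [", paste(x$fit_diagnostics$flags, collapse = ", "), "]")
    } else {
      ""
    }))
  invisible(x)
}

#' Fit the logistic rise of a RUSH trace
#'
#' Least-squares fit of `f(x) = y0 + (ymax - y0) / (1 + (x_half/x)^n)`
#' over the window from the first frame to two frames past the trace
#' maximum. Samples at `t <= 0` are excluded (the model is undefined at
#' `x = 0`) and the exclusion recorded in the diagnostics. Initialization:
#' `y0` = first value, `ymax` = max value, `x_half` = time of half-range
#' crossing, `n = 4`; bounded restarts with jittered starts on failure.
#'
#' @param trace a [timed_trace()] in minutes.
#' @param max_restarts jittered restarts before giving up.
#' @return a partial `rush_fit` (logistic block filled in).
#' @export
fit_logistic <- function(trace, max_restarts = 10L) {
  stopifnot(inherits(trace, "timed_trace"))
  t <- trace$times
  y <- trace$values
  i_max <- which.max(y)
  win <- seq_len(min(length(y), i_max + 2L))
  t_w <- t[win]; y_w <- y[win]
  excluded_t0 <- any(t_w <= 0)
  keep <- t_w > 0
  t_w <- t_w[keep]; y_w <- y_w[keep]
  if (length(t_w) < 6L) {
    stop("need at least 6 positive-time samples in the fit window",
         call. = FALSE)
  }
  y0_init <- y_w[1L]
  ymax_init <- max(y_w)
  half <- (y0_init + ymax_init) / 2
  x_half_init <- t_w[which(y_w >= half)[1L]]
  if (!is.finite(x_half_init) || x_half_init <= 0) {
    x_half_init <- stats::median(t_w)
  }
  fit1 <- function(start) {
    df <- data.frame(t = t_w, y = y_w)
    stats::nls(y ~ y0 + (ymax - y0) / (1 + (x_half / t)^n),
               data = df, start = start, algorithm = "port",
               lower = c(y0 = -0.5, ymax = 1e-6, x_half = min(t_w) / 10,
                         n = 1e-3),
               upper = c(y0 = max(y_w), ymax = 2 * max(y_w),
                         x_half = 10 * max(t_w), n = 50),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE))
  }
  start <- list(y0 = y0_init, ymax = ymax_init, x_half = x_half_init, n = 4)
  fit <- NULL
  last_err <- NULL
  for (r in 0:max_restarts) {
    st <- if (r == 0L) start else with_seed(1000 + r, list(
      y0 = y0_init * runif(1, 0.5, 1.5),
      ymax = ymax_init * runif(1, 0.8, 1.2),
      x_half = x_half_init * runif(1, 0.5, 2),
      n = runif(1, 1, 10)))
    fit <- tryCatch(fit1(st), error = function(e) {
      last_err <<- conditionMessage(e)
      NULL
    })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("logistic fit failed to converge after restarts: ", last_err,
         call. = FALSE)
  }
  p <- as.list(stats::coef(fit))
  out <- new_rush_fit()
  out$y0 <- p$y0; out$ymax <- p$ymax; out$x_half <- p$x_half; out$n <- p$n
  out$fit_diagnostics$rss <- sum(stats::resid(fit)^2)
  out$fit_diagnostics$converged <- TRUE
  out$fit_diagnostics$n_window <- length(t_w)
  out$fit_diagnostics$argmax_index <- i_max
  if (excluded_t0) {
    out$fit_diagnostics$flags <- c(out$fit_diagnostics$flags, "t0_excluded")
  }
  out
}

#' Fit a line to the post-peak tail of a RUSH trace
#'
#' Ordinary least squares `y = a + b * x` from the trace maximum to the
#' last frame, describing Golgi-to-PM export.
#'
#' @param trace a [timed_trace()] in minutes.
#' @param fit a `rush_fit` from [fit_logistic()] (carries the argmax
#'   index); recomputed from the trace if absent.
#' @return `fit` with the line block (`a`, `b`) filled in.
#' @export
fit_tail_line <- function(trace, fit = NULL) {
  stopifnot(inherits(trace, "timed_trace"))
  if (is.null(fit)) fit <- new_rush_fit()
  i_max <- fit$fit_diagnostics$argmax_index
  if (is.null(i_max)) i_max <- which.max(trace$values)
  tail_idx <- i_max:length(trace$values)
  if (length(tail_idx) < 3L) {
    stop("need at least 3 samples after the trace maximum", call. = FALSE)
  }
  co <- stats::coef(stats::lm.fit(
    cbind(1, trace$times[tail_idx]),
    trace$values[tail_idx]))
  fit$a <- unname(co[1L])
  fit$b <- unname(co[2L])
  fit$fit_diagnostics$n_tail <- length(tail_idx)
  fit
}

#' Derive the three transport half-times
#'
#' `t1/2(ER->Golgi)` is the fitted `x_half`. `t1/2(ER->PM)` is the time at
#' which the declining tail line crosses the logistic half-maximum value
#' `(y0 + ymax)/2`: solve `a + b*t = (y0 + ymax)/2`. The Golgi transit
#' time is their difference. If the line does not decline (`b >= 0`) or
#' crosses before `x_half`, the ER->PM time is flagged undefined rather
#' than fabricated.
#'
#' @param fit a `rush_fit` with logistic and line blocks present.
#' @return the completed `rush_fit`.
#' @export
transport_halftimes <- function(fit) {
  stopifnot(inherits(fit, "rush_fit"))
  if (!is.finite(fit$x_half) || !is.finite(fit$b)) {
    stop("logistic and line blocks must be fitted first", call. = FALSE)
  }
  fit$t_half_er_golgi <- fit$x_half
  half_y <- (fit$y0 + fit$ymax) / 2
  if (fit$b >= 0) {
    fit$fit_diagnostics$flags <- c(fit$fit_diagnostics$flags,
                                   "er_pm_undefined_nondeclining_tail")
    return(fit)
  }
  t_pm <- (half_y - fit$a) / fit$b
  if (!is.finite(t_pm) || t_pm <= fit$x_half) {
    fit$fit_diagnostics$flags <- c(fit$fit_diagnostics$flags,
                                   "er_pm_undefined_crossing_before_x_half")
    return(fit)
  }
  fit$t_half_er_pm <- t_pm
  fit$golgi_transit <- t_pm - fit$x_half
  fit
}

#' Full RUSH analysis of one trace
#'
#' Logistic fit, tail line fit, and half-time derivation in one call.
#'
#' @param trace a [timed_trace()] in minutes.
#' @return a completed `rush_fit`.
#' @export
rush_analyze <- function(trace) {
  fit <- fit_logistic(trace)
  fit <- fit_tail_line(trace, fit)
  transport_halftimes(fit)
}

#' Turn a list of RUSH fits into a per-cell results table
#'
#' @param fits list of `rush_fit` objects (named by cell/trace id).
#' @return data.frame with one row per fit.
#' @export
rush_results_table <- function(fits) {
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    id <- names(fits)[i]
    if (is.null(id) || !nzchar(id)) id <- sprintf("trace%d", i)
    data.frame(trace_id = id, y0 = f$y0, ymax = f$ymax, x_half = f$x_half,
               n = f$n, a = f$a, b = f$b,
               t_half_er_golgi = f$t_half_er_golgi,
               t_half_er_pm = f$t_half_er_pm,
               golgi_transit = f$golgi_transit,
               rss = f$fit_diagnostics$rss,
               converged = f$fit_diagnostics$converged,
               flags = paste(f$fit_diagnostics$flags, collapse = ";"))
  }))
}
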