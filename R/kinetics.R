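# Rerouting and FRAP trace kinetics: ROI aggregation, photobleach
# correction, FRAP normalization, single- and double-exponential fits.

#' Mean-intensity traces from ROI sets
#'
#' Averages pixel intensity per frame over a set of mitochondrial ROIs and
#' a set of cytoplasmic ROIs (the rerouting assay uses ten 10x10-px boxes
#' on mitochondria and several free-form cytoplasmic boxes). Each ROI is a
#' list `(x, y, w, h)` in 0-based pixel coordinates; the trace value is
#' the mean of the per-ROI means.
#'
#' @param stack an [image_stack()] `[y, x, t]`.
#' @param mito_rois,cyto_rois lists of ROI boxes.
#' @param frame_interval seconds per frame.
#' @return list with elements `mito` and `cyto`, both [timed_trace()]s.
#' @export
roi_mean_traces <- function(stack, mito_rois, cyto_rois,
                            frame_interval = 1) {
  dims <- dim(stack)
  roi_means <- function(rois, set) {
    per_roi <- vapply(seq_along(rois), function(i) {
      r <- rois[[i]]
      x0 <- r$x + 1L; y0 <- r$y + 1L
      x1 <- r$x + r$w; y1 <- r$y + r$h
      if (r$x < 0 || r$y < 0 || x1 > dims[2L] || y1 > dims[1L]) {
        stop(sprintf("%s ROI %d (x=%d y=%d w=%d h=%d) out of bounds",
                     set, i, r$x, r$y, r$w, r$h), call. = FALSE)
      }
      apply(stack[y0:y1, x0:x1, , drop = FALSE], 3L, mean)
    }, numeric(dims[3L]))
    rowMeans(per_roi)
  }
  times <- frame_interval * (seq_len(dims[3L]) - 1L)
  list(mito = timed_trace(times, roi_means(mito_rois, "mito"), unit = "s",
                          meta = list(trace_id = "mito")),
       cyto = timed_trace(times, roi_means(cyto_rois, "cyto"), unit = "s",
                          meta = list(trace_id = "cyto")))
}

#' Simple-ratio photobleach correction
#'
#' Corrects a trace by the fractional decay of a reference region:
#' `corrected(t) = trace(t) * reference(t0) / reference(t)`. The first
#' frame is the anchor, so `corrected(t0) = trace(t0)` always, and a
#' constant reference leaves the trace unchanged.
#'
#' @param trace a [timed_trace()].
#' @param reference a [timed_trace()] of the same length, all values
#'   `> 0`; defaults to the trace's own embedded `reference` series.
#' @return the corrected [timed_trace()].
#' @export
bleach_correct_simple_ratio <- function(trace, reference = NULL) {
  stopifnot(inherits(trace, "timed_trace"))
  ref <- if (is.null(reference)) {
    trace$reference
  } else if (inherits(reference, "timed_trace")) {
    reference$values
  } else {
    as.numeric(reference)
  }
  if (is.null(ref)) stop("no reference series available", call. = FALSE)
  if (length(ref) != length(trace$times)) {
    stop("reference must match trace length", call. = FALSE)
  }
  bad <- which(ref <= 0)
  if (length(bad)) {
    stop(sprintf("reference is <= 0 at sample %d", bad[1L]), call. = FALSE)
  }
  out <- trace
  out$values <- trace$values * ref[1L] / ref
  out$reference <- NULL
  out
}

new_exp_fit <- function() {
  structure(list(tau = NA_real_, tau_fast = NA_real_, tau_slow = NA_real_,
                 fraction_slow = NA_real_, baseline = NA_real_,
                 amplitude = NA_real_, chi2 = NA_real_,
                 mobile_fraction = NA_real_, t_half = NA_real_,
                 converged = FALSE, flags = character(0)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (is.finite(x$tau_fast)) {
    cat(sprintf(
      "<exp_fit double> M=%.3g tau_fast=%.4g s tau_slow=%.4g s f_slow=%.3g t1/2=%.4g s chi2=%.3g\n",
      x$mobile_fraction, x$tau_fast, x$tau_slow, x$fraction_slow,
      x$t_half, x$chi2))
  } else {
    cat(sprintf(
      "<exp_fit single> baseline=%.4g amplitude=%.4g tau=%.4g s chi2=%.3g\n",
      x$baseline, x$amplitude, x$tau, x$chi2))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# chi2 here is RSS / (N - k): residual variance; the original pipeline
# statistic is not defined in its methods.
reduced_chi2 <- function(resid, k) {
  sum(resid^2) / max(1L, length(resid) - k)
}

#' Fit a single exponential to a rerouting trace
#'
#' Fits `y(t) = baseline + amplitude * (1 - exp(-(t - t_event)/tau))` to
#' the samples at `t >= t_event` (rapamycin addition). The amplitude sign
#' is free, so decaying cytoplasmic traces fit with `amplitude < 0`.
#'
#' @param trace a [timed_trace()] in seconds.
#' @param t_event event time (seconds); default 0.
#' @param max_restarts jittered restarts before giving up.
#' @return an `exp_fit` with `tau`, `baseline`, `amplitude`, `chi2`.
#' @export
fit_single_exponential <- function(trace, t_event = 0, max_restarts = 10L) {
  stopifnot(inherits(trace, "timed_trace"))
  keep <- trace$times >= t_event
  t <- trace$times[keep] - t_event
  y <- trace$values[keep]
  if (length(t) < 6L) {
    stop("need at least 6 samples after t_event", call. = FALSE)
  }
  out <- new_exp_fit()
  amp_init <- y[length(y)] - y[1L]
  if (abs(amp_init) < 1e-12 * max(abs(y), 1)) {
    out$flags <- "amplitude_unidentifiable"
    out$baseline <- mean(y)
    out$amplitude <- 0
    return(out)
  }
  # crossing of 63% of the range estimates tau
  target <- y[1L] + 0.632 * amp_init
  idx <- if (amp_init > 0) which(y >= target)[1L] else which(y <= target)[1L]
  tau_init <- if (is.finite(idx) && !is.na(idx) && t[idx] > 0) {
    t[idx]
  } else {
    max(t) / 3
  }
  df <- data.frame(t = t, y = y)
  fit <- NULL
  last_err <- NULL
  for (r in 0:max_restarts) {
    st <- if (r == 0L) {
      list(baseline = y[1L], amplitude = amp_init, tau = tau_init)
    } else {
      with_seed(2000 + r, list(baseline = y[1L] * runif(1, 0.8, 1.2),
                               amplitude = amp_init * runif(1, 0.5, 1.5),
                               tau = tau_init * runif(1, 0.2, 5)))
    }
    fit <- tryCatch(
      stats::nls(y ~ baseline + amplitude * (1 - exp(-t / tau)), data = df,
                 start = st, algorithm = "port",
                 lower = c(baseline = -Inf, amplitude = -Inf,
                           tau = max(t) * 1e-6),
                 upper = c(baseline = Inf, amplitude = Inf,
                           tau = max(t) * 100),
                 control = stats::nls.control(maxiter = 200)),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("single-exponential fit failed to converge: ", last_err,
         call. = FALSE)
  }
  p <- as.list(stats::coef(fit))
  out$tau <- p$tau
  out$baseline <- p$baseline
  out$amplitude <- p$amplitude
  out$chi2 <- reduced_chi2(stats::resid(fit), 3L)
  out$converged <- TRUE
  out
}

#' Normalize a FRAP trace
#'
#' Background-subtracts the bleached ROI and whole-cell traces, forms the
#' ratio `r = (frap - bg) / (cell - bg)` (correcting for the fluorescence
#' destroyed by the bleach pulse itself), then rescales so the value at
#' `bleach_index` is 0 and the mean of the first five (pre-bleach) frames
#' is 1. Times are shifted so the bleach frame is `t = 0` and pre-bleach
#' frames are dropped from the output.
#'
#' @param frap_roi,whole_cell,background [timed_trace()]s on the same time
#'   base (background may also be a constant).
#' @param bleach_index 1-based index of the first post-bleach frame.
#' @return a normalized [timed_trace()] starting at the bleach frame.
#' @export
normalize_frap <- function(frap_roi, whole_cell, background, bleach_index) {
  stopifnot(inherits(frap_roi, "timed_trace"))
  n <- length(frap_roi$times)
  bg <- if (inherits(background, "timed_trace")) {
    background$values
  } else {
    rep_len(as.numeric(background), n)
  }
  cell <- if (inherits(whole_cell, "timed_trace")) {
    whole_cell$values
  } else {
    as.numeric(whole_cell)
  }
  if (length(cell) != n || length(bg) != n) {
    stop("series must be aligned to the FRAP trace", call. = FALSE)
  }
  if (bleach_index <= 5L || bleach_index > n) {
    stop("need >= 5 pre-bleach frames and a valid bleach_index",
         call. = FALSE)
  }
  bad <- which(cell - bg <= 0)
  if (length(bad)) {
    stop(sprintf("whole-cell signal <= background at frame %d", bad[1L]),
         call. = FALSE)
  }
  r <- (frap_roi$values - bg) / (cell - bg)
  pre <- mean(r[1:5])
  r0 <- r[bleach_index]
  if (abs(pre - r0) < 1e-12 * max(abs(pre), 1)) {
    stop("degenerate scaling: pre-bleach mean equals bleach value (no bleach event?)",
         call. = FALSE)
  }
  scaled <- (r - r0) / (pre - r0)
  idx <- bleach_index:n
  timed_trace(frap_roi$times[idx] - frap_roi$times[bleach_index],
              scaled[idx], unit = "s",
              meta = c(frap_roi$meta, list(normalized = TRUE)))
}

#' Fit a double exponential to a normalized FRAP trace
#'
#' Fits `y(t) = M * (f * (1 - exp(-t/tau_fast)) + (1 - f) *
#' (1 - exp(-t/tau_slow)))` to a normalized recovery starting at 0.
#' `tau_fast <= tau_slow` is enforced by reordering after the fit (removes
#' label switching); `t_half` is the time at which recovery reaches `M/2`,
#' solved numerically. If the double fit cannot converge the function
#' falls back to a single exponential with an explicit flag.
#'
#' @param trace a normalized [timed_trace()] (first value near 0).
#' @param max_restarts jittered restarts before the fallback.
#' @return an `exp_fit` with `mobile_fraction`, `tau_fast`, `tau_slow`,
#'   `fraction_slow`, `t_half`, `chi2`.
#' @export
fit_double_exponential <- function(trace, max_restarts = 12L) {
  stopifnot(inherits(trace, "timed_trace"))
  t <- trace$times - trace$times[1L]
  y <- trace$values
  if (length(t) < 8L) stop("need at least 8 samples", call. = FALSE)
  df <- data.frame(t = t, y = y)
  plateau <- mean(y[t >= stats::quantile(t, 0.8)])
  fit <- NULL
  for (r in 0:max_restarts) {
    st <- if (r == 0L) {
      list(M = min(max(plateau, 0.05), 1.05), f = 0.3,
           tf = max(t) / 50, ts = max(t) / 3)
    } else {
      with_seed(3000 + r, list(M = min(max(plateau, 0.05), 1.05) *
                                 runif(1, 0.8, 1.1),
                               f = runif(1, 0.05, 0.95),
                               tf = max(t) / 50 * runif(1, 0.1, 10),
                               ts = max(t) / 3 * runif(1, 0.3, 3)))
    }
    fit <- tryCatch(
      stats::nls(y ~ M * (f * (1 - exp(-t / tf)) + (1 - f) *
                            (1 - exp(-t / ts))),
                 data = df, start = st, algorithm = "port",
                 lower = c(M = 0, f = 0, tf = max(t) * 1e-7,
                           ts = max(t) * 1e-7),
                 upper = c(M = 1.05, f = 1, tf = max(t) * 100,
                           ts = max(t) * 100),
                 control = stats::nls.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  out <- new_exp_fit()
  if (is.null(fit)) {
    # "singular convergence": the two components have collapsed onto an
    # identifiable ridge; port's estimates are still least-squares
    # optimal along it, so accept them with a flag
    fit <- tryCatch(suppressWarnings(
      stats::nls(y ~ M * (f * (1 - exp(-t / tf)) + (1 - f) *
                            (1 - exp(-t / ts))),
                 data = df,
                 start = list(M = min(max(plateau, 0.05), 1.05), f = 0.3,
                              tf = max(t) / 50, ts = max(t) / 3),
                 algorithm = "port",
                 lower = c(M = 0, f = 0, tf = max(t) * 1e-7,
                           ts = max(t) * 1e-7),
                 upper = c(M = 1.05, f = 1, tf = max(t) * 100,
                           ts = max(t) * 100),
                 control = stats::nls.control(maxiter = 500,
                                              warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) out$flags <- c(out$flags, "relaxed_convergence")
  }
  if (is.null(fit)) {
    single <- fit_single_exponential(trace, t_event = trace$times[1L])
    out <- single
    out$mobile_fraction <- max(0, min(1.05, single$baseline +
                                        single$amplitude))
    out$flags <- c(out$flags, "double_fit_fallback_single")
    return(out)
  }
  p <- as.list(stats::coef(fit))
  if (p$tf > p$ts) {  # reorder so tau_fast <= tau_slow
    tmp <- p$tf; p$tf <- p$ts; p$ts <- tmp
    p$f <- 1 - p$f
  }
  out$mobile_fraction <- p$M
  out$tau_fast <- p$tf
  out$tau_slow <- p$ts
  out$fraction_slow <- 1 - p$f
  out$chi2 <- reduced_chi2(stats::resid(fit), 4L)
  out$converged <- TRUE
  model <- function(tt) {
    p$M * (p$f * (1 - exp(-tt / p$tf)) + (1 - p$f) * (1 - exp(-tt / p$ts)))
  }
  if (p$M > 0) {
    out$t_half <- tryCatch(
      stats::uniroot(function(tt) model(tt) - p$M / 2,
                     lower = 0, upper = max(t) * 1000,
                     tol = 1e-10)$root,
      error = function(e) NA_real_)
  }
  out
}
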