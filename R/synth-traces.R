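# Synthetic kinetic traces: RUSH (logistic rise, linear decline) and
# mono-/multi-exponential rerouting / FRAP recovery.

# Logistic transport model: f(x) = y0 + (ymax - y0) / (1 + (x_half/x)^n).
# Undefined at x = 0; the right limit is y0, which we use there.
logistic_model <- function(x, y0, ymax, x_half, n) {
  out <- rep(y0, length(x))
  pos <- x > 0
  out[pos] <- y0 + (ymax - y0) / (1 + (x_half / x[pos])^n)
  out
}

#' Generate a synthetic RUSH Golgi-fraction trace
#'
#' Emulates the Golgi fluorescence fraction of a pulse-released secretory
#' cargo: a logistic rise (ER-to-Golgi filling) up to the time the logistic
#' reaches 99% of its plateau, followed by a linear decline (Golgi-to-PM
#' export). Additive Gaussian noise of standard deviation `cfg$noise_sd`
#' (the trace is already a dimensionless fraction) is applied on top.
#'
#' @param y0 baseline fraction at release, `>= 0`.
#' @param ymax plateau fraction, `> y0`.
#' @param x_half time (minutes) at which the logistic reaches its midpoint
#'   `(y0 + ymax)/2`.
#' @param n Hill-like exponent controlling rise steepness, `> 0`.
#' @param decay_slope slope of the post-peak linear decline
#'   (fraction/minute), `<= 0`.
#' @param cfg a [synth_config()]; `frame_interval` is in minutes.
#' @return a [timed_trace()] in minutes with `ground_truth` carrying all
#'   generator parameters plus the computed `t_peak`.
#' @examples
#' tr <- gen_rush_trace(0.05, 0.6, x_half = 20, n = 6, decay_slope = -0.01,
#'                      cfg = synth_config(seed = 7, frame_interval = 0.5,
#'                                         n_samples = 160))
#' @export
gen_rush_trace <- function(y0, ymax, x_half, n, decay_slope,
                           cfg = synth_config()) {
  stopifnot_scalar(y0, "y0", nonneg = TRUE)
  stopifnot_scalar(ymax, "ymax")
  stopifnot_scalar(x_half, "x_half", positive = TRUE)
  stopifnot_scalar(n, "n", positive = TRUE)
  stopifnot_scalar(decay_slope, "decay_slope")
  if (ymax <= y0) stop("ymax must exceed y0", call. = FALSE)
  if (decay_slope > 0) stop("decay_slope must be <= 0", call. = FALSE)
  times <- cfg$frame_interval * seq(0L, cfg$n_samples - 1L)
  # Time at which the logistic reaches 0.99 * ymax (requires 0.99*ymax > y0);
  # beyond it the trace declines linearly.
  thr <- 0.99 * ymax
  if (thr <= y0) stop("0.99 * ymax must exceed y0", call. = FALSE)
  ratio <- (ymax - y0) / (thr - y0) - 1
  t_peak <- x_half / ratio^(1 / n)
  y <- logistic_model(times, y0, ymax, x_half, n)
  post <- times > t_peak
  y_peak <- logistic_model(t_peak, y0, ymax, x_half, n)
  y[post] <- y_peak + decay_slope * (times[post] - t_peak)
  noisy <- with_seed(cfg$seed, y + rnorm(length(y), sd = cfg$noise_sd))
  timed_trace(
    times, noisy, unit = "min",
    meta = list(trace_id = sprintf("rush_seed%d", cfg$seed),
                condition = "synthetic"),
    ground_truth = list(y0 = y0, ymax = ymax, x_half = x_half, n = n,
                        decay_slope = decay_slope, t_peak = t_peak,
                        noise_sd = cfg$noise_sd, model = y)
  )
}

#' Generate a synthetic exponential recovery/rerouting trace
#'
#' Mono- or multi-exponential approach from `baseline` to
#' `baseline + amplitude`, with an optional multiplicative photobleach
#' envelope `exp(-t/bleach_tau)` applied both to the signal and to an
#' emitted constant reference trace (so downstream bleach correction can be
#' tested against ground truth). Additive Gaussian noise has standard
#' deviation `cfg$noise_sd * |amplitude|`.
#'
#' @param baseline pre-event intensity (a.u.).
#' @param amplitude total change (a.u.); negative for decaying signals.
#' @param taus vector of time constants (seconds), all `> 0`.
#' @param fractions amplitude fractions per component, summing to 1.
#' @param bleach_tau photobleach time constant (seconds) or `NULL` for no
#'   bleaching.
#' @param cfg a [synth_config()]; `frame_interval` is in seconds.
#' @return a [timed_trace()] in seconds; `reference` holds the bleach
#'   envelope (constantly 1 when `bleach_tau` is `NULL`).
#' @examples
#' tr <- gen_exponential_trace(10, 50, taus = 38, fractions = 1,
#'                             cfg = synth_config(seed = 2, n_samples = 200))
#' @export
gen_exponential_trace <- function(baseline, amplitude, taus, fractions = 1,
                                  bleach_tau = NULL,
                                  cfg = synth_config()) {
  stopifnot_scalar(baseline, "baseline")
  stopifnot_scalar(amplitude, "amplitude")
  if (length(taus) != length(fractions)) {
    stop("taus and fractions must have the same length", call. = FALSE)
  }
  if (any(taus <= 0)) stop("all taus must be > 0", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  if (!is.null(bleach_tau)) {
    stopifnot_scalar(bleach_tau, "bleach_tau", positive = TRUE)
  }
  times <- cfg$frame_interval * seq(0L, cfg$n_samples - 1L)
  rec <- rowSums(vapply(seq_along(taus), function(i) {
    fractions[i] * (1 - exp(-times / taus[i]))
  }, numeric(length(times))))
  y <- baseline + amplitude * rec
  envelope <- if (is.null(bleach_tau)) rep(1, length(times)) else
    exp(-times / bleach_tau)
  y <- y * envelope
  noisy <- with_seed(cfg$seed,
                     y + rnorm(length(y), sd = cfg$noise_sd * abs(amplitude)))
  timed_trace(
    times, noisy, unit = "s", reference = envelope,
    meta = list(trace_id = sprintf("exp_seed%d", cfg$seed),
                condition = "synthetic"),
    ground_truth = list(baseline = baseline, amplitude = amplitude,
                        taus = taus, fractions = fractions,
                        bleach_tau = bleach_tau,
                        noise_sd = cfg$noise_sd, model = y)
  )
}

#' Generate a synthetic normalized FRAP trace
#'
#' Convenience wrapper producing a post-bleach recovery curve on the
#' normalized scale (0 at the bleach frame) with a known mobile fraction:
#' `y(t) = M * (f * (1 - exp(-t/tau_fast)) + (1 - f) * (1 - exp(-t/tau_slow)))`.
#'
#' @param mobile_fraction total recoverable fraction `M` in `[0, 1]`.
#' @param fraction_fast fraction `f` of recovery via the fast process.
#' @param tau_fast,tau_slow time constants (seconds).
#' @param cfg a [synth_config()]; noise SD is `cfg$noise_sd * M`.
#' @return a [timed_trace()] in seconds starting at `t = 0` (bleach frame).
#' @export
gen_frap_trace <- function(mobile_fraction, fraction_fast, tau_fast,
                           tau_slow, cfg = synth_config()) {
  if (mobile_fraction < 0 || mobile_fraction > 1.05) {
    stop("mobile_fraction must lie in [0, 1.05]", call. = FALSE)
  }
  if (fraction_fast < 0 || fraction_fast > 1) {
    stop("fraction_fast must lie in [0, 1]", call. = FALSE)
  }
  tr <- gen_exponential_trace(
    baseline = 0, amplitude = mobile_fraction,
    taus = c(tau_fast, tau_slow),
    fractions = c(fraction_fast, 1 - fraction_fast),
    bleach_tau = NULL, cfg = cfg
  )
  tr$ground_truth <- c(tr$ground_truth,
                       list(mobile_fraction = mobile_fraction,
                            fraction_fast = fraction_fast,
                            tau_fast = tau_fast, tau_slow = tau_slow))
  tr$meta$trace_id <- sprintf("frap_seed%d", cfg$seed)
  tr
}
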