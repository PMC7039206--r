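#' Timed intensity trace
#'
#' The common currency of all kinetics stages: a `(time, value)` series with
#' a time unit, an optional parallel reference series (e.g. an unbleached
#' control region used for photobleach correction), and provenance metadata.
#'
#' @param times numeric vector of strictly increasing time points.
#' @param values numeric vector of intensities (arbitrary units), same
#'   length as `times`, all finite.
#' @param unit time unit, `"s"` or `"min"`.
#' @param reference optional numeric reference series, same length.
#' @param meta named list of provenance fields (`trace_id`, `cell_id`,
#'   `condition`, ...). Free-form; carried through unchanged.
#' @param ground_truth optional named list of true generator parameters,
#'   attached when the trace is synthetic.
#'
#' @return an object of class `timed_trace`.
#' @examples
#' tr <- timed_trace(0:10, exp(-(0:10) / 4), unit = "s")
#' length(tr$times)
#' @export
timed_trace <- function(times, values, unit = c("s", "min"),
                        reference = NULL, meta = list(),
                        ground_truth = NULL) {
  unit <- match.arg(unit)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have the same length", call. = FALSE)
  }
  if (length(times) < 1L) {
    stop("a trace needs at least one sample", call. = FALSE)
  }
  if (any(!is.finite(times))) {
    stop("times must be finite", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  if (!is.null(reference)) {
    reference <- as.numeric(reference)
    if (length(reference) != length(times)) {
      stop("reference must have the same length as times", call. = FALSE)
    }
  }
  structure(
    list(times = times, values = values, unit = unit,
         reference = reference, meta = meta,
         ground_truth = ground_truth),
    class = "timed_trace"
  )
}

#' @export
print.timed_trace <- function(x, ...) {
  cat(sprintf("<timed_trace> %d samples, t = %g..%g %s%s\n",
              length(x$times), x$times[1L],
              x$times[length(x$times)], x$unit,
              if (!is.null(x$reference)) ", with reference" else ""))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.timed_trace <- function(x) length(x$times)

#' Extract stored ground truth
#'
#' Every synthetic artifact carries the generating parameters alongside the
#' data, so downstream parameter-recovery tests never re-run the generator.
#'
#' @param x a synthetic object (trace, scene, image, stack, or table).
#' @return named list of true parameter values, or `NULL` if the object is
#'   not synthetic.
#' @export
ground_truth <- function(x) {
  gt <- attr(x, "ground_truth", exact = TRUE)
  if (!is.null(gt)) return(gt)
  if (is.list(x) && !is.null(x$ground_truth)) return(x$ground_truth)
  NULL
}

#' Synthetic-data configuration
#'
#' Shared knobs for all generators. A fixed `seed` makes every generator
#' byte-reproducible; `noise_sd` is a relative noise amplitude whose exact
#' meaning is documented per generator (additive Gaussian for traces); and
#' `frame_interval`/`n_samples` set the sampling grid for time series.
#'
#' @param seed integer RNG seed.
#' @param noise_sd relative additive noise level, `>= 0`.
#' @param frame_interval sampling interval (seconds or minutes depending on
#'   the assay), `> 0`.
#' @param n_samples number of samples, `>= 2`.
#' @return an object of class `synth_config`.
#' @examples
#' cfg <- synth_config(seed = 1, noise_sd = 0.02, frame_interval = 0.5,
#'                     n_samples = 120)
#' @export
synth_config <- function(seed = 1L, noise_sd = 0, frame_interval = 1,
                         n_samples = 100L) {
  stopifnot_scalar(seed, "seed")
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  stopifnot_scalar(n_samples, "n_samples")
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  structure(
    list(seed = as.integer(seed), noise_sd = noise_sd,
         frame_interval = frame_interval, n_samples = as.integer(n_samples)),
    class = "synth_config"
  )
}
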