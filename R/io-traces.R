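# CSV reader/writer for timed traces. Long format: one row per sample,
# traces distinguished by trace_id.

#' Read traces from a CSV table
#'
#' Expects a header with at least `time` and `value` columns; optional
#' `reference`, `trace_id`, `cell_id`, `condition`. Rows with a missing
#' `value` are dropped with a warning reporting the count; duplicate or
#' non-increasing timestamps within a trace are an error.
#'
#' @param path CSV file.
#' @param unit time unit of the `time` column (`"s"` or `"min"`); the file
#'   itself carries no unit, so it comes from configuration.
#' @return a named list of [timed_trace()] objects, one per `trace_id`
#'   (a single unnamed trace if the column is absent).
#' @export
read_trace_table <- function(path, unit = c("s", "min")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "value") %in% names(df))) {
    stop("trace table needs 'time' and 'value' columns", call. = FALSE)
  }
  n_miss <- sum(is.na(df$value) | is.na(df$time))
  if (n_miss > 0L) {
    warning(sprintf("dropped %d row(s) with missing time/value", n_miss),
            call. = FALSE)
    df <- df[!(is.na(df$value) | is.na(df$time)), , drop = FALSE]
  }
  if (!"trace_id" %in% names(df)) df$trace_id <- "trace1"
  out <- list()
  for (id in unique(df$trace_id)) {
    sub <- df[df$trace_id == id, , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    if (any(diff(sub$time) <= 0)) {
      stop(sprintf("trace '%s' has duplicate or non-increasing timestamps",
                   id), call. = FALSE)
    }
    meta <- list(trace_id = id)
    for (f in c("cell_id", "condition")) {
      if (f %in% names(sub)) meta[[f]] <- sub[[f]][1L]
    }
    ref <- if ("reference" %in% names(sub) && !all(is.na(sub$reference))) {
      sub$reference
    } else {
      NULL
    }
    out[[id]] <- timed_trace(sub$time, sub$value, unit = unit,
                             reference = ref, meta = meta)
  }
  out
}

#' Write traces to a CSV table
#'
#' Inverse of [read_trace_table()]. Values round-trip to better than 1e-9
#' relative (written with full double precision).
#'
#' @param traces a [timed_trace()] or list of them.
#' @param path output CSV file.
#' @export
write_trace_table <- function(traces, path) {
  if (inherits(traces, "timed_trace")) traces <- list(traces)
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    id <- tr$meta$trace_id
    if (is.null(id)) id <- names(traces)[i]
    if (is.null(id) || !nzchar(id)) id <- sprintf("trace%d", i)
    df <- data.frame(time = tr$times, value = tr$values, trace_id = id)
    df$reference <- if (is.null(tr$reference)) NA_real_ else tr$reference
    for (f in c("cell_id", "condition")) {
      df[[f]] <- if (is.null(tr$meta[[f]])) NA_character_ else tr$meta[[f]]
    }
    df
  })
  df <- do.call(rbind, rows)
  # full precision so numeric round-trips are lossless to ~1e-15
  old <- options(digits = 17)
  on.exit(options(old))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seed, input file hashes and package version
#' of a CLI run, as JSON next to the outputs.
#'
#' @param path output `.json` path.
#' @param config named list of the effective configuration.
#' @param inputs character vector of input file paths (md5-hashed).
#' @param seed the RNG seed used, if any.
#' @export
write_manifest <- function(path, config = list(), inputs = character(0),
                           seed = NULL) {
  hashes <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else {
    list()
  }
  manifest <- list(
    package = "invquant",
    version = as.character(utils::packageVersion("invquant")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_md5 = hashes)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
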