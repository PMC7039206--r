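#' Per-cell vesicle-capture screen table
#'
#' One row per cell: construct label, trial label, and mitochondrial
#' fluorescence before (`F_pre`) and after (`F_post`) rapamycin. The
#' derived per-cell statistic is the ratio `F_post / F_pre`.
#'
#' @param df data.frame with columns `cell_id`, `construct`, `trial`,
#'   `F_pre`, `F_post`.
#' @param control name of the control construct (default `"GFP"`); must be
#'   present in every trial.
#' @param ground_truth optional generator parameters.
#' @return `df` with class `screen_table` and a `ratio` column added.
#' @export
screen_table <- function(df, control = "GFP", ground_truth = NULL) {
  need <- c("cell_id", "construct", "trial", "F_pre", "F_post")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("screen table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$F_pre <= 0)) stop("F_pre must be > 0", call. = FALSE)
  trials <- unique(df$trial)
  for (tr in trials) {
    if (!control %in% df$construct[df$trial == tr]) {
      stop(sprintf("control construct '%s' missing from trial '%s'",
                   control, tr), call. = FALSE)
    }
  }
  df$ratio <- df$F_post / df$F_pre
  structure(df, control = control, ground_truth = ground_truth,
            class = c("screen_table", "data.frame"))
}

#' Generate a synthetic Rab-screen table
#'
#' Per-cell pre-rapamycin mitochondrial intensity is lognormal around a
#' common baseline; the post-rapamycin intensity is
#' `F_pre * fold_change * exp(N(0, cell_sd))`, so `fold_change` is the true
#' median per-cell capture ratio for that construct. Cells are split evenly
#' across `trials` experimental repeats.
#'
#' @param constructs character vector of construct names; must include the
#'   control.
#' @param fold_changes true `F_post / F_pre` per construct (recycled),
#'   all `> 0`.
#' @param n_cells cells per construct per trial, `>= 3`.
#' @param trials number of experimental repeats.
#' @param cell_sd SD of the per-cell lognormal ratio scatter.
#' @param control control construct name (default `"GFP"`).
#' @param baseline_log_mean,baseline_log_sd lognormal baseline of `F_pre`.
#' @param cfg a [synth_config()]; only `seed` is used.
#' @return a [screen_table()] with ground truth.
#' @examples
#' tab <- gen_screen_table(c("GFP", "Rab30"), c(1, 2.5), n_cells = 10,
#'                         cfg = synth_config(seed = 5))
#' @export
gen_screen_table <- function(constructs, fold_changes, n_cells = 25L,
                             trials = 3L, cell_sd = 0.25, control = "GFP",
                             baseline_log_mean = log(100),
                             baseline_log_sd = 0.3,
                             cfg = synth_config()) {
  if (any(fold_changes <= 0)) stop("fold_changes must be > 0", call. = FALSE)
  if (n_cells < 3L) stop("n_cells must be >= 3", call. = FALSE)
  fold_changes <- rep_len(fold_changes, length(constructs))
  with_seed(cfg$seed, {
    rows <- list()
    cell <- 0L
    for (ci in seq_along(constructs)) {
      for (tr in seq_len(trials)) {
        f_pre <- exp(rnorm(n_cells, baseline_log_mean, baseline_log_sd))
        f_post <- f_pre * fold_changes[ci] * exp(rnorm(n_cells, 0, cell_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = sprintf("cell%04d", cell + seq_len(n_cells)),
          construct = constructs[ci],
          trial = sprintf("trial%d", tr),
          F_pre = f_pre, F_post = f_post)
        cell <- cell + n_cells
      }
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    screen_table(
      df, control = control,
      ground_truth = list(
        constructs = constructs, fold_changes = fold_changes,
        # E[ratio] for a lognormal scatter exceeds the median fold change
        mean_ratios = fold_changes * exp(cell_sd^2 / 2),
        n_cells = n_cells, trials = trials, cell_sd = cell_sd,
        seed = cfg$seed))
  })
}
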