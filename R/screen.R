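# Rab-screen statistics: per-cell mitochondrial intensity ratios,
# permutation many-to-one (Dunnett-style) tests against the GFP control,
# and mean-difference effect sizes with BCa bootstrap intervals.

#' Mitochondrial intensity ratio
#'
#' The per-cell capture statistic: mitochondrial fluorescence after
#' rapamycin divided by the value before.
#'
#' @param F_pre,F_post numeric vectors (a.u.), `F_pre > 0`.
#' @return `F_post / F_pre`.
#' @export
mito_ratio <- function(F_pre, F_post) {
  if (any(F_pre <= 0)) stop("F_pre must be > 0", call. = FALSE)
  F_post / F_pre
}

# ratios for one construct; optionally per trial
construct_ratios <- function(table, construct, trial = NULL) {
  sel <- table$construct == construct
  if (!is.null(trial)) sel <- sel & table$trial == trial
  list(ratio = table$ratio[sel], trial = table$trial[sel])
}

#' BCa bootstrap effect size of a construct versus control
#'
#' Statistic: mean capture ratio of the construct minus mean ratio of the
#' control, pooled over trials. Bootstrap resamples the two groups
#' independently (stratified by trial when trial labels are present,
#' respecting the experimental structure); the bias-corrected and
#' accelerated interval uses the bias term `z0` (normal quantile of the
#' fraction of resamples below the observed statistic) and the
#' acceleration `a` from jackknife skewness over the pooled leave-one-out
#' statistics. Degenerate cases (zero-variance groups, or a resample
#' distribution entirely to one side of the observed statistic) fall back
#' to the percentile interval with an explicit flag.
#'
#' @param table a [screen_table()].
#' @param construct construct label to compare.
#' @param control control label (default from the table, usually
#'   `"GFP"`).
#' @param n_boot bootstrap replications (default 1e5, the original
#'   analysis' count).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the resampling.
#' @param stratify resample within trials (default `TRUE`).
#' @return list of class `effect_size`: `construct`, `mean_diff`,
#'   `ci_low`, `ci_high`, `n_cells`, `n_control`, `z0`, `accel`,
#'   `method` (`"bca"` or `"percentile"`), `flag`.
#' @export
effect_size_bca <- function(table, construct, control = NULL,
                            n_boot = 1e5, conf = 0.95, seed = 1L,
                            stratify = TRUE) {
  stopifnot(inherits(table, "screen_table"))
  if (is.null(control)) control <- attr(table, "control")
  g1 <- construct_ratios(table, construct)
  g0 <- construct_ratios(table, control)
  if (length(g1$ratio) < 5L || length(g0$ratio) < 5L) {
    stop("construct and control each need >= 5 cells", call. = FALSE)
  }
  obs <- mean(g1$ratio) - mean(g0$ratio)
  flag <- NULL
  # stratified group-mean resampler: bootstrap means per trial stratum,
  # combined with the observed stratum weights
  boot_means <- function(vals, trials, B) {
    # values are sorted within each stratum so the resample stream -- and
    # hence the interval -- is invariant to relabeling of cells
    if (!stratify || length(unique(trials)) < 2L) {
      v <- sort(vals)
      n <- length(v)
      idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
      return(colMeans(matrix(v[idx], nrow = n)))
    }
    total <- length(vals)
    acc <- numeric(B)
    for (tr in sort(unique(trials))) {
      v <- sort(vals[trials == tr])
      n <- length(v)
      idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
      acc <- acc + colSums(matrix(v[idx], nrow = n))
    }
    acc / total
  }
  boot <- with_seed(seed, {
    boot_means(g1$ratio, g1$trial, n_boot) -
      boot_means(g0$ratio, g0$trial, n_boot)
  })
  alpha <- (1 - conf) / 2
  if (stats::sd(g1$ratio) == 0 && stats::sd(g0$ratio) == 0) {
    flag <- "degenerate_zero_variance"
  }
  frac_below <- mean(boot < obs)
  if (is.null(flag) && (frac_below == 0 || frac_below == 1)) {
    flag <- "degenerate_bias_correction"
  }
  if (!is.null(flag)) {
    ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
    return(structure(list(construct = construct, mean_diff = obs,
                          ci_low = ci[1L], ci_high = ci[2L],
                          n_cells = length(g1$ratio),
                          n_control = length(g0$ratio),
                          z0 = NA_real_, accel = NA_real_,
                          method = "percentile", flag = flag),
                     class = "effect_size"))
  }
  z0 <- stats::qnorm(frac_below)
  # jackknife over the pooled sample: delete one cell from either group
  n1 <- length(g1$ratio); n0 <- length(g0$ratio)
  s1 <- sum(g1$ratio); s0 <- sum(g0$ratio)
  jk <- c((s1 - g1$ratio) / (n1 - 1) - s0 / n0,
          s1 / n1 - (s0 - g0$ratio) / (n0 - 1))
  d <- mean(jk) - jk
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  zl <- stats::qnorm(alpha)
  zu <- stats::qnorm(1 - alpha)
  a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  ci <- stats::quantile(boot, c(a1, a2), names = FALSE)
  structure(list(construct = construct, mean_diff = obs,
                 ci_low = ci[1L], ci_high = ci[2L],
                 n_cells = n1, n_control = n0,
                 z0 = z0, accel = a, method = "bca", flag = flag),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> %s: %.4g [%.4g, %.4g] (%s, n=%d vs %d)%s\n",
              x$construct, x$mean_diff, x$ci_low, x$ci_high, x$method,
              x$n_cells, x$n_control,
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Permutation many-to-one comparisons against the control
#'
#' Dunnett-style family-wise comparisons of every construct against the
#' control within one trial, implemented as a max-t permutation test:
#' Welch t statistics per construct, null distribution from permuting all
#' cell labels within the trial, and each p-value read off the maximum
#' |t| over the family (which converges to Dunnett's test under
#' exchangeability while staying exact for small non-Normal samples).
#'
#' @param table a [screen_table()].
#' @param trial trial label, or `NULL` for all data pooled.
#' @param control control label (default from the table).
#' @param n_perm permutations (default 1e4).
#' @param seed RNG seed.
#' @return data.frame with `construct`, `t`, `p_adj` (family-wise), `n`.
#' @export
dunnett_vs_control <- function(table, trial = NULL, control = NULL,
                               n_perm = 1e4, seed = 1L) {
  stopifnot(inherits(table, "screen_table"))
  if (is.null(control)) control <- attr(table, "control")
  df <- if (is.null(trial)) table else table[table$trial == trial, ,
                                             drop = FALSE]
  counts <- table(df$construct)
  small <- setdiff(names(counts)[counts < 3L], character(0))
  if (length(small)) {
    warning("excluded constructs with < 3 cells: ",
            paste(small, collapse = ", "), call. = FALSE)
    df <- df[!df$construct %in% small, , drop = FALSE]
  }
  constructs <- setdiff(unique(df$construct), control)
  if (!length(constructs) || !control %in% df$construct) {
    stop("need the control plus at least one other construct",
         call. = FALSE)
  }
  vals <- df$ratio
  grp <- df$construct
  welch_t <- function(x, y) {
    (mean(x) - mean(y)) /
      sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  }
  t_obs <- vapply(constructs, function(cc) {
    welch_t(vals[grp == cc], vals[grp == control])
  }, numeric(1))
  max_t <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    pg <- sample(grp)
    max(abs(vapply(constructs, function(cc) {
      welch_t(vals[pg == cc], vals[pg == control])
    }, numeric(1))))
  }, numeric(1)))
  p_adj <- vapply(abs(t_obs), function(ti) {
    (1 + sum(max_t >= ti)) / (n_perm + 1)
  }, numeric(1))
  data.frame(construct = constructs, t = unname(t_obs),
             p_adj = unname(p_adj),
             n = as.integer(counts[constructs]),
             row.names = NULL)
}

#' Co-rerouting correlation of a Rab against TPD54
#'
#' OLS line fit of the per-cell Rab co-rerouting ratio on the TPD54
#' rerouting ratio, reported against the `y = x` identity line, with a
#' qualitative classification of the relationship: `"rising"` (the Rab
#' tracks TPD54), `"high-flat"` (constitutively co-rerouted), or
#' `"low-flat"` (not co-rerouted).
#'
#' @param tpd54_ratio,rab_ratio paired per-cell ratios (>= 5 cells).
#' @param slope_threshold slope above which the relation is `"rising"`.
#' @param high_threshold intercept above which a flat relation is
#'   `"high-flat"`.
#' @return list: `slope`, `intercept`, `r_squared`, `se_slope`,
#'   `classification`, `n`.
#' @export
rerouting_correlation <- function(tpd54_ratio, rab_ratio,
                                  slope_threshold = 0.3,
                                  high_threshold = 1.5) {
  if (length(tpd54_ratio) != length(rab_ratio)) {
    stop("inputs must be paired", call. = FALSE)
  }
  if (length(tpd54_ratio) < 5L) stop("need >= 5 paired cells",
                                     call. = FALSE)
  if (stats::var(tpd54_ratio) == 0) {
    stop("zero variance in the TPD54 ratios", call. = FALSE)
  }
  fit <- stats::lm(rab_ratio ~ tpd54_ratio)
  co <- stats::coef(fit)
  se <- summary(fit)$coefficients[2L, 2L]
  slope <- unname(co[2L]); intercept <- unname(co[1L])
  classification <- if (slope > slope_threshold) {
    "rising"
  } else if (intercept > high_threshold) {
    "high-flat"
  } else {
    "low-flat"
  }
  list(slope = slope, intercept = intercept,
       r_squared = summary(fit)$r.squared, se_slope = se,
       classification = classification, n = length(tpd54_ratio))
}

#' Full screen analysis
#'
#' Pooled BCa effect sizes for every construct against the control
#' (sorted by descending effect, the ranking view), per-trial and pooled
#' permutation-Dunnett p-values, and the hit call (pooled BCa interval
#' excluding 0).
#'
#' @param table a [screen_table()].
#' @param control control label (default from the table).
#' @param n_boot bootstrap replications for the BCa intervals.
#' @param n_perm permutations for the Dunnett-style tests.
#' @param seed RNG seed.
#' @return data.frame, one row per construct: effect size, CI, hit flag,
#'   pooled and per-trial adjusted p-values.
#' @export
screen_analyze <- function(table, control = NULL, n_boot = 1e5,
                           n_perm = 1e4, seed = 1L) {
  stopifnot(inherits(table, "screen_table"))
  if (is.null(control)) control <- attr(table, "control")
  constructs <- setdiff(unique(table$construct), control)
  eff <- lapply(seq_along(constructs), function(i) {
    effect_size_bca(table, constructs[i], control, n_boot = n_boot,
                    seed = derive_seed(seed, i))
  })
  out <- do.call(rbind, lapply(eff, function(e) {
    data.frame(construct = e$construct, mean_diff = e$mean_diff,
               ci_low = e$ci_low, ci_high = e$ci_high,
               n_cells = e$n_cells, method = e$method,
               hit = e$ci_low > 0 | e$ci_high < 0)
  }))
  pooled <- dunnett_vs_control(table, trial = NULL, control = control,
                               n_perm = n_perm,
                               seed = derive_seed(seed, 9001))
  out$p_pooled <- pooled$p_adj[match(out$construct, pooled$construct)]
  for (tr in unique(table$trial)) {
    ptr <- dunnett_vs_control(table, trial = tr, control = control,
                              n_perm = n_perm,
                              seed = derive_seed(seed, 9002))
    out[[paste0("p_", tr)]] <- ptr$p_adj[match(out$construct,
                                               ptr$construct)]
  }
  out[order(-out$mean_diff), , drop = FALSE]
}
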