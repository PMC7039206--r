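# Screen statistics: ratios, BCa effect sizes, permutation Dunnett,
# co-rerouting correlation.

test_that("mito_ratio is the post/pre quotient", {
  expect_equal(mito_ratio(5, 5), 1)
  expect_equal(mito_ratio(c(2, 4), c(5, 2)), c(2.5, 0.5))
  expect_error(mito_ratio(0, 1), "F_pre")
  tab <- gen_screen_table(c("GFP", "R"), c(1, 1.8), n_cells = 30,
                          trials = 1, cell_sd = 0.2,
                          cfg = synth_config(seed = 101))
  r <- tab$ratio[tab$construct == "R"]
  expect_lt(abs(mean(r) - ground_truth(tab)$mean_ratios[2]),
            3 * sd(r) / sqrt(length(r)))
})

test_that("effect_size_bca behaves on identical and shifted groups", {
  # null effect: the interval should cover 0 in most replicates
  covers <- vapply(1:10, function(s) {
    tab <- gen_screen_table(c("GFP", "Null"), c(1, 1), n_cells = 30,
                            cfg = synth_config(seed = 1100 + s))
    e <- effect_size_bca(tab, "Null", n_boot = 2000, seed = 7)
    expect_lte(e$ci_low, e$mean_diff)
    expect_gte(e$ci_high, e$mean_diff)
    e$ci_low < 0 && e$ci_high > 0
  }, logical(1))
  expect_gte(sum(covers), 8)
  # literally identical groups: zero mean difference
  df <- data.frame(cell_id = sprintf("c%d", 1:20),
                   construct = rep(c("GFP", "X"), each = 10),
                   trial = "t1", F_pre = rep(1, 20),
                   F_post = rep(c(1.0, 1.1, 1.2, 1.3, 1.4), 4))
  tab2 <- screen_table(df)
  e2 <- effect_size_bca(tab2, "X", n_boot = 2000, seed = 1)
  expect_equal(e2$mean_diff, 0)
  expect_true(e2$ci_low <= 0 && e2$ci_high >= 0)
})

test_that("effect_size_bca is deterministic and relabeling invariant", {
  tab <- gen_screen_table(c("GFP", "R"), c(1, 1.6), n_cells = 20,
                          cfg = synth_config(seed = 103))
  e1 <- effect_size_bca(tab, "R", n_boot = 3000, seed = 11)
  e2 <- effect_size_bca(tab, "R", n_boot = 3000, seed = 11)
  expect_identical(e1[c("mean_diff", "ci_low", "ci_high")],
                   e2[c("mean_diff", "ci_low", "ci_high")])
  # shuffling rows leaves the interval unchanged (values are sorted
  # within strata before resampling)
  perm <- withr::with_seed(5, sample(nrow(tab)))
  tab_shuf <- screen_table(as.data.frame(tab)[perm,
                                              c("cell_id", "construct",
                                                "trial", "F_pre",
                                                "F_post")])
  e3 <- effect_size_bca(tab_shuf, "R", n_boot = 3000, seed = 11)
  expect_equal(e3$ci_low, e1$ci_low)
  expect_equal(e3$ci_high, e1$ci_high)
})

test_that("BCa is asymmetric toward the long tail on skewed groups", {
  # construct group with strongly right-skewed ratios
  set.seed(104)
  n <- 40
  df <- data.frame(
    cell_id = sprintf("c%d", 1:(2 * n)),
    construct = rep(c("GFP", "Skew"), each = n),
    trial = "t1", F_pre = 1,
    F_post = c(rnorm(n, 2, 0.05), 2 + rexp(n, rate = 1)))
  tab <- screen_table(df)
  e <- effect_size_bca(tab, "Skew", n_boot = 20000, seed = 3)
  expect_gt(e$ci_high - e$mean_diff, e$mean_diff - e$ci_low)
  expect_equal(e$method, "bca")
})

test_that("widening the confidence level widens the BCa interval", {
  tab <- gen_screen_table(c("GFP", "R"), c(1, 1.4), n_cells = 25,
                          cfg = synth_config(seed = 105))
  e95 <- effect_size_bca(tab, "R", n_boot = 4000, seed = 2, conf = 0.95)
  e99 <- effect_size_bca(tab, "R", n_boot = 4000, seed = 2, conf = 0.99)
  expect_lte(e99$ci_low, e95$ci_low)
  expect_gte(e99$ci_high, e95$ci_high)
})

test_that("BCa approaches the percentile interval on symmetric data", {
  set.seed(106)
  n <- 200
  df <- data.frame(cell_id = sprintf("c%d", 1:(2 * n)),
                   construct = rep(c("GFP", "S"), each = n),
                   trial = "t1", F_pre = 1,
                   F_post = c(rnorm(n, 1, 0.2), rnorm(n, 1.5, 0.2)))
  tab <- screen_table(df)
  e <- effect_size_bca(tab, "S", n_boot = 1e4, seed = 4)
  boot_sd <- 0.2 * sqrt(2 / n)
  # z0 and acceleration are near zero, so BCa ~ percentile
  expect_lt(abs(e$z0), 0.1)
  expect_lt(abs(e$accel), 0.05)
  expect_lt(abs((e$ci_high - e$ci_low) - 2 * 1.96 * boot_sd), boot_sd)
})

test_that("permutation Dunnett matches exhaustive enumeration at 4+4", {
  vals <- c(1.2, 1.5, 1.1, 1.4, 2.1, 1.9, 2.3, 1.8)
  df <- data.frame(cell_id = sprintf("c%d", 1:8),
                   construct = rep(c("GFP", "X"), each = 4),
                   trial = "t1", F_pre = 1, F_post = vals)
  tab <- screen_table(df)
  res <- dunnett_vs_control(tab, n_perm = 20000, seed = 8)
  welch_t <- function(x, y) (mean(x) - mean(y)) /
    sqrt(var(x) / 4 + var(y) / 4)
  t_obs <- abs(welch_t(vals[5:8], vals[1:4]))
  combs <- combn(8, 4)
  t_all <- apply(combs, 2, function(ix) {
    abs(welch_t(vals[-ix], vals[ix]))
  })
  p_exact <- mean(t_all >= t_obs - 1e-12)
  expect_lt(abs(res$p_adj - p_exact), 3 * sqrt(p_exact * (1 - p_exact) /
                                                 20000) + 1e-3)
})

test_that("permutation Dunnett detects a large shift and excludes tiny groups", {
  set.seed(107)
  hits <- vapply(1:60, function(s) {
    tab <- gen_screen_table(c("GFP", "A", "B"), c(1, 1, 1), n_cells = 20,
                            trials = 1, cell_sd = 0.2,
                            cfg = synth_config(seed = 2000 + s))
    # shift construct B by ~3 SD of the ratio scatter
    tab$F_post[tab$construct == "B"] <-
      tab$F_post[tab$construct == "B"] * exp(3 * 0.2)
    tab$ratio <- tab$F_post / tab$F_pre
    res <- dunnett_vs_control(tab, n_perm = 500, seed = s)
    res$p_adj[res$construct == "B"] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.95)
  df <- data.frame(cell_id = sprintf("c%d", 1:24),
                   construct = c(rep("GFP", 10), rep("A", 12),
                                 rep("Tiny", 2)),
                   trial = "t1", F_pre = 1, F_post = rnorm(24, 2, 0.2))
  tab2 <- screen_table(df)
  expect_warning(res2 <- dunnett_vs_control(tab2, n_perm = 200, seed = 1),
                 "Tiny")
  expect_false("Tiny" %in% res2$construct)
})

test_that("rerouting_correlation classifies the relationship shape", {
  x <- seq(1, 3, length.out = 20)
  p <- suppressWarnings(rerouting_correlation(x, x))  # exact fit warns
  expect_equal(p$slope, 1, tolerance = 1e-9)
  expect_equal(p$intercept, 0, tolerance = 1e-9)
  expect_equal(p$classification, "rising")
  flat <- suppressWarnings(
    rerouting_correlation(x, rep(2, 20) + rnorm(20, 0, 1e-8)))
  expect_equal(flat$slope, 0, tolerance = 1e-6)
  expect_equal(flat$intercept, 2, tolerance = 1e-6)
  expect_equal(flat$classification, "high-flat")
  low <- suppressWarnings(
    rerouting_correlation(x, rep(1, 20) + rnorm(20, 0, 1e-8)))
  expect_equal(low$classification, "low-flat")
  set.seed(108)
  y <- 0.5 + 0.8 * x + rnorm(20, 0, 0.1)
  noisy <- rerouting_correlation(x, y)
  expect_lt(abs(noisy$slope - 0.8), 3 * noisy$se_slope)
  expect_error(rerouting_correlation(rep(1, 10), rnorm(10)),
               "zero variance")
  expect_error(rerouting_correlation(1:3, 1:3), ">= 5")
})

test_that("screen_analyze ranks constructs and calls hits", {
  tab <- gen_screen_table(c("GFP", "Rab30", "Rab2a", "RabX"),
                          c(1, 2.5, 1.4, 1), n_cells = 20,
                          cfg = synth_config(seed = 109))
  res <- screen_analyze(tab, n_boot = 3000, n_perm = 1000, seed = 5)
  expect_equal(res$construct[1], "Rab30")
  expect_true(all(diff(res$mean_diff) <= 0))
  expect_true(res$hit[res$construct == "Rab30"])
  expect_true(res$hit[res$construct == "Rab2a"])
  expect_false(res$hit[res$construct == "RabX"])
  expect_true(all(c("p_pooled", "p_trial1") %in% names(res)))
})
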