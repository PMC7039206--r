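# Rerouting/FRAP stage: ROI traces, bleach correction, exponential fits,
# FRAP normalization.

test_that("roi_mean_traces averages ROI sets per frame", {
  stack <- image_stack(array(5, dim = c(40, 40, 10)))
  rois10 <- lapply(0:9, function(i) list(x = (i %% 4) * 10, y = (i %/% 4) * 10,
                                         w = 10, h = 10))
  cyto <- list(list(x = 0, y = 30, w = 20, h = 10))
  trs <- roi_mean_traces(stack, rois10, cyto, frame_interval = 2)
  expect_equal(trs$mito$values, rep(5, 10))
  expect_equal(trs$cyto$values, rep(5, 10))
  expect_equal(trs$mito$times, seq(0, 18, by = 2))
  # one ROI on a 2v structure, nine on background v -> mean 1.1 v
  arr <- array(5, dim = c(40, 40, 3))
  arr[1:10, 1:10, ] <- 10
  trs2 <- roi_mean_traces(image_stack(arr), rois10, cyto)
  expect_equal(trs2$mito$values, rep((10 + 9 * 5) / 10, 3))
  bad <- list(list(x = 35, y = 0, w = 10, h = 10))
  expect_error(roi_mean_traces(stack, bad, cyto), "ROI 1")
})

test_that("simple-ratio bleach correction inverts a shared envelope", {
  cfg <- synth_config(seed = 51, noise_sd = 0, frame_interval = 1,
                      n_samples = 150)
  tr <- gen_exponential_trace(10, 50, 38, 1, bleach_tau = 80, cfg = cfg)
  corrected <- bleach_correct_simple_ratio(tr)
  unbleached <- 10 + 50 * (1 - exp(-tr$times / 38))
  expect_lt(max(abs(corrected$values - unbleached)), 1e-12)
  # anchor: first frame unchanged; constant reference is a no-op
  expect_equal(corrected$values[1], tr$values[1])
  tr2 <- timed_trace(0:9, rnorm(10), unit = "s")
  same <- bleach_correct_simple_ratio(tr2, rep(3, 10))
  expect_equal(same$values, tr2$values)
  # idempotence given a constant reference
  expect_equal(bleach_correct_simple_ratio(same, rep(3, 10))$values,
               same$values)
  expect_error(bleach_correct_simple_ratio(tr2, c(rep(1, 9), 0)),
               "sample 10")
})

test_that("single-exponential fits recover tau", {
  cfg <- synth_config(seed = 52, noise_sd = 0, frame_interval = 0.5,
                      n_samples = 400)
  tr <- gen_exponential_trace(20, 80, 38, 1, cfg = cfg)
  fit <- fit_single_exponential(tr)
  expect_rel_equal(c(fit$tau, fit$baseline, fit$amplitude), c(38, 20, 80),
                   1e-6)
  # decaying (cytoplasmic) signals fit with negative amplitude
  trd <- gen_exponential_trace(100, -40, 47.5, 1, cfg = cfg)
  fitd <- fit_single_exponential(trd)
  expect_rel_equal(fitd$tau, 47.5, 1e-6)
  expect_lt(fitd$amplitude, 0)
  # degenerate flat trace: flagged, not fitted
  flat <- timed_trace(seq(0, 10, by = 1), rep(5, 11), unit = "s")
  ff <- fit_single_exponential(flat)
  expect_false(ff$converged)
  expect_true("amplitude_unidentifiable" %in% ff$flags)
  # time-translation equivariance via t_event
  shifted <- timed_trace(tr$times + 100, tr$values, unit = "s")
  fs <- fit_single_exponential(shifted, t_event = 100)
  expect_rel_equal(fs$tau, fit$tau, 1e-9)
})

test_that("single-tau recovery stays under 5% error at SNR 10", {
  errs <- vapply(1:50, function(s) {
    tr <- gen_exponential_trace(10, 50, 38, 1,
                                cfg = synth_config(seed = s,
                                                   noise_sd = 0.1,
                                                   frame_interval = 1,
                                                   n_samples = 200))
    abs(fit_single_exponential(tr)$tau - 38) / 38
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("normalize_frap applies the stated scaling", {
  n <- 60
  times <- seq(0, by = 0.5, length.out = n)
  recovery <- c(rep(1, 10), 0.8 * (1 - exp(-(times[11:n] - times[11]) / 5)))
  cell <- rep(1000, n)
  bg <- rep(50, n)
  frap <- bg + (cell - bg) * recovery
  out <- normalize_frap(timed_trace(times, frap, unit = "s"),
                        timed_trace(times, cell, unit = "s"),
                        timed_trace(times, bg, unit = "s"),
                        bleach_index = 11)
  expect_equal(out$values[1], 0)
  expect_equal(out$times[1], 0)
  # known mobile fraction recovered at the plateau
  expect_equal(out$values[length(out$values)], 0.8, tolerance = 0.01)
  # flat trace: degenerate scaling is an error
  expect_error(normalize_frap(timed_trace(times, cell, unit = "s"),
                              timed_trace(times, cell * 2, unit = "s"),
                              timed_trace(times, bg, unit = "s"), 11),
               "degenerate")
  expect_error(normalize_frap(timed_trace(times, frap, unit = "s"),
                              timed_trace(times, bg, unit = "s"),
                              timed_trace(times, bg, unit = "s"), 11),
               "background")
})

test_that("double-exponential fits recover all four parameters", {
  cfg <- synth_config(seed = 53, noise_sd = 0, frame_interval = 0.25,
                      n_samples = 600)
  tr <- gen_frap_trace(0.9, 0.2, 2, 40, cfg)
  fit <- fit_double_exponential(tr)
  expect_rel_equal(c(fit$mobile_fraction, fit$tau_fast, fit$tau_slow,
                     fit$fraction_slow), c(0.9, 2, 40, 0.8), 1e-4)
  expect_lte(fit$tau_fast, fit$tau_slow)
  # t_half solves y(t) = M/2
  y_at <- 0.9 * (0.2 * (1 - exp(-fit$t_half / 2)) +
                   0.8 * (1 - exp(-fit$t_half / 40)))
  expect_equal(y_at, 0.45, tolerance = 1e-6)
  # equal taus degenerate to a single exponential
  tr1 <- gen_frap_trace(0.8, 0.5, 10, 10, cfg)
  fit1 <- fit_double_exponential(tr1)
  model <- fit1$mobile_fraction *
    ((1 - fit1$fraction_slow) * (1 - exp(-tr1$times / fit1$tau_fast)) +
       fit1$fraction_slow * (1 - exp(-tr1$times / fit1$tau_slow)))
  single <- 0.8 * (1 - exp(-tr1$times / 10))
  expect_lt(max(abs(model - single)), 1e-4)
  expect_rel_equal(fit1$mobile_fraction, 0.8, 1e-4)
})

test_that("slow-tau recovery stays under 15% error at SNR 10", {
  errs <- vapply(1:40, function(s) {
    tr <- gen_frap_trace(0.9, 0.2, 2, 40,
                         synth_config(seed = s, noise_sd = 0.1,
                                      frame_interval = 0.25,
                                      n_samples = 480))
    abs(fit_double_exponential(tr)$tau_slow - 40) / 40
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})
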