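# Generators: determinism, stated identities, and noise calibration.

test_that("gen_rush_trace honors the logistic midpoint and determinism", {
  cfg <- synth_config(seed = 1, noise_sd = 0, frame_interval = 0.5,
                      n_samples = 160)
  tr <- gen_rush_trace(0.1, 0.7, x_half = 20, n = 6, decay_slope = -0.01,
                      cfg = cfg)
  expect_equal(tr$values[tr$times == 20], (0.1 + 0.7) / 2)
  tr2 <- gen_rush_trace(0.1, 0.7, 20, 6, -0.01, cfg = cfg)
  expect_identical(tr$values, tr2$values)
  expect_error(gen_rush_trace(0.1, 0.7, -1, 6, -0.01, cfg), "x_half")
  expect_error(gen_rush_trace(0.1, 0.7, 20, -1, -0.01, cfg), "n must")
  expect_error(gen_rush_trace(0.1, 0.7, 20, 6, 0.5, cfg), "decay_slope")
})

test_that("rush noise calibration matches the requested SD", {
  resid <- unlist(lapply(1:1000, function(s) {
    cfg <- synth_config(seed = s, noise_sd = 0.01, frame_interval = 2,
                        n_samples = 30)
    tr <- gen_rush_trace(0.05, 0.6, 20, 6, -0.01, cfg)
    tr$values - ground_truth(tr)$model
  }))
  expect_lt(abs(sd(resid) - 0.01) / 0.01, 0.05)
})

test_that("gen_exponential_trace matches its closed form", {
  cfg <- synth_config(seed = 2, noise_sd = 0, frame_interval = 1,
                      n_samples = 200)
  tr <- gen_exponential_trace(10, 50, taus = 38, fractions = 1, cfg = cfg)
  expect_equal(tr$values[tr$times == 38], 10 + 50 * (1 - exp(-1)))
  expect_true(all(tr$reference == 1))
  tr2 <- gen_exponential_trace(0, 1, taus = c(2, 40),
                               fractions = c(0.2, 0.8), cfg = cfg)
  closed <- 0.2 * (1 - exp(-tr2$times / 2)) + 0.8 * (1 - exp(-tr2$times / 40))
  expect_lt(max(abs(tr2$values - closed)), 1e-12)
  expect_error(gen_exponential_trace(0, 1, taus = c(2, 40), fractions = 1,
                                     cfg = cfg), "length")
  expect_error(gen_exponential_trace(0, 1, taus = 2, fractions = 0.7,
                                     cfg = cfg), "sum to 1")
  # bleach envelope multiplies signal and reference alike
  trb <- gen_exponential_trace(10, 50, 38, 1, bleach_tau = 100, cfg = cfg)
  expect_equal(trb$reference, exp(-trb$times / 100))
})

test_that("gen_em_scene places vesicles as stated", {
  # no vesicles: mitochondrion only, decorated fraction 0
  sc0 <- gen_em_scene(0, cfg = synth_config(seed = 1))
  expect_length(invquant:::scene_contours(sc0, "vesicle"), 0)
  expect_equal(decorated_fraction(sc0)$decorated_fraction, 0)
  # capture_fraction = 1: every vesicle boundary within 15 nm of the mito
  sc1 <- gen_em_scene(15, 30, 5, capture_fraction = 1, scale = 2,
                      cfg = synth_config(seed = 2))
  mito <- invquant:::scene_contours(sc1, "mitochondrion")[[1]]
  for (ct in invquant:::scene_contours(sc1, "vesicle")) {
    d <- min(invquant:::dist_to_polyline(ct[, 1] * 2, ct[, 2] * 2,
                                         mito[, 1] * 2, mito[, 2] * 2))
    expect_lte(d, 15)
  }
  # capture_fraction = 0: all vesicles >= 100 nm away
  sc2 <- gen_em_scene(10, 30, 5, capture_fraction = 0, scale = 1,
                      cfg = synth_config(seed = 3))
  mito2 <- invquant:::scene_contours(sc2, "mitochondrion")[[1]]
  for (ct in invquant:::scene_contours(sc2, "vesicle")) {
    d <- min(invquant:::dist_to_polyline(ct[, 1], ct[, 2],
                                         mito2[, 1], mito2[, 2]))
    expect_gte(d, 100 - 1e-6)
  }
  # diameter distribution: pooled ground truth within 3 SE of the mean
  diams <- unlist(lapply(1:20, function(s) {
    sc <- gen_em_scene(25, 30, 9.4, capture_fraction = 0.4,
                       cfg = synth_config(seed = 100 + s))
    ground_truth(sc)$vesicles$diameter_nm
  }))
  expect_gte(length(diams), 500)
  se <- 9.4 / sqrt(length(diams))
  # truncation at 2*scale trims the lower tail, raising the mean slightly
  expect_lt(abs(mean(diams) - 30), 3 * se + 0.15)
  expect_identical(
    ground_truth(gen_em_scene(5, cfg = synth_config(seed = 9)))$vesicles,
    ground_truth(gen_em_scene(5, cfg = synth_config(seed = 9)))$vesicles)
})

test_that("gen_localization_image places and counts spots correctly", {
  img <- gen_localization_image(1, sigma = 24, pixel_size = 16,
                                field = c(1, 1), counts_per_spot = 1000,
                                shot_noise = FALSE,
                                cfg = synth_config(seed = 4))
  gt <- ground_truth(img)
  am <- which(img$pixels == max(img$pixels), arr.ind = TRUE)
  expect_lte(abs(unname(am[1, "col"]) - 1 - gt$x_px), 0.5 + 1e-9)
  expect_lte(abs(unname(am[1, "row"]) - 1 - gt$y_px), 0.5 + 1e-9)
  # density arithmetic from the assay's reporting convention
  expect_identical(spots_for_density(26.8, 100), 268L)
  # total counts conserved within Poisson error
  img2 <- gen_localization_image(20, sigma = 24, pixel_size = 16,
                                 field = c(4, 4), counts_per_spot = 500,
                                 cfg = synth_config(seed = 5))
  total <- 20 * 500
  expect_lt(abs(sum(img2$pixels) - total), 3 * sqrt(total) + 60)
  expect_error(gen_localization_image(50, sigma = 24, pixel_size = 16,
                                      field = c(0.5, 0.5),
                                      cfg = synth_config(seed = 6)),
               "field too small")
})

test_that("gen_flicker_stack modes behave as designed", {
  s0 <- gen_flicker_stack("uniform", shot_noise = FALSE,
                          cfg = synth_config(seed = 7))
  expect_equal(flicker_variance(s0)$mean_variance, 0)
  s1 <- gen_flicker_stack("uniform", cfg = synth_config(seed = 7))
  s1b <- gen_flicker_stack("uniform", cfg = synth_config(seed = 7))
  expect_identical(unclass(s1), unclass(s1b))
  sv <- gen_flicker_stack("vesicles", cfg = synth_config(seed = 7))
  # matched mean intensity by construction, flicker metric > 2x uniform
  expect_equal(mean(sv), mean(s1), tolerance = 0.05)
  expect_gt(flicker_variance(sv)$mean_variance /
              flicker_variance(s1)$mean_variance, 2)
})

test_that("gen_screen_table encodes its fold changes", {
  tab <- gen_screen_table(c("GFP", "Rab30"), c(1, 2.5), n_cells = 70,
                          trials = 3, cell_sd = 0.25,
                          cfg = synth_config(seed = 8))
  gt <- ground_truth(tab)
  r <- tab$ratio[tab$construct == "Rab30"]
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - gt$mean_ratios[2]), 3 * se)
  tab2 <- gen_screen_table(c("GFP", "Rab30"), c(1, 2.5), n_cells = 70,
                           trials = 3, cell_sd = 0.25,
                           cfg = synth_config(seed = 8))
  expect_identical(tab$F_post, tab2$F_post)
  # null construct: effect sizes centered on zero
  tab0 <- gen_screen_table(c("GFP", "A", "B"), 1, n_cells = 60,
                           cell_sd = 0.2, cfg = synth_config(seed = 9))
  for (cc in c("A", "B")) {
    m <- mean(tab0$ratio[tab0$construct == cc]) -
      mean(tab0$ratio[tab0$construct == "GFP"])
    expect_lt(abs(m), 3 * 0.2 / sqrt(60))
  }
})
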