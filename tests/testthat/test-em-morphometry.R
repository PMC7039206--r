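# EM morphometry: diameters, perimeter, abundance, decorated fraction.

regular_polygon <- function(r, n, cx = 0, cy = 0, phase = 0) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + phase
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang), z = 0)
}

square_contour <- function(side_px, cx = 0, cy = 0, pts_per_edge = 25) {
  s <- side_px / 2
  t <- seq(0, 1, length.out = pts_per_edge + 1)[-(pts_per_edge + 1)]
  cbind(x = cx + c(-s + t * side_px, rep(s, pts_per_edge),
                   s - t * side_px, rep(-s, pts_per_edge)),
        y = cy + c(rep(-s, pts_per_edge), -s + t * side_px,
                   rep(s, pts_per_edge), s - t * side_px),
        z = 0)
}

test_that("vesicle_diameter is the polar-radius average", {
  vm <- vesicle_diameter(regular_polygon(15, 32), scale = 1)
  expect_lt(abs(vm$diameter - 30) / 30, 0.002)
  expect_equal(vm$n_points, 32)
  # ellipse: compare against a dense numerical mean-radius oracle
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  ell <- cbind(10 * cos(th), 20 * sin(th), 0)
  vm2 <- vesicle_diameter(ell, scale = 1)
  th_dense <- seq(0, 2 * pi, length.out = 1e6 + 1)[-(1e6 + 1)]
  oracle <- 2 * mean(sqrt((10 * cos(th_dense))^2 + (20 * sin(th_dense))^2))
  expect_lt(abs(vm2$diameter - oracle) / oracle, 0.005)
  # scale converts px to nm
  expect_equal(vesicle_diameter(regular_polygon(15, 32), scale = 2)$diameter,
               60, tolerance = 1e-9)
  expect_error(vesicle_diameter(cbind(1:5, 2 * (1:5), 0), scale = 1),
               "collinear")
})

test_that("mito_perimeter sums closed polyline lengths", {
  sq <- square_contour(1000)  # 1 um x 1 um at 1 nm/px
  expect_equal(mito_perimeter(list(sq), scale = 1), 4)
  # additivity over disjoint contours
  sq2 <- square_contour(500, cx = 5000)
  expect_equal(mito_perimeter(list(sq, sq2), scale = 1), 4 + 2)
  # matches an independent arc-length oracle on a random smooth blob
  set.seed(61)
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  r <- 300 * (1 + 0.2 * sin(3 * th) + 0.1 * cos(5 * th))
  blob <- cbind(r * cos(th), r * sin(th), 0)
  oracle <- sum(sqrt(diff(c(blob[, 1], blob[1, 1]))^2 +
                       diff(c(blob[, 2], blob[1, 2]))^2)) / 1000
  expect_equal(mito_perimeter(list(blob), scale = 1), oracle,
               tolerance = 1e-9)
})

test_that("vesicles_per_micron divides count by perimeter", {
  mk_scene <- function(n_ves) {
    ves <- lapply(seq_len(n_ves), function(i) {
      regular_polygon(15, 16, cx = 3000 + 100 * i, cy = 3000)
    })
    objs <- list(list(label = "mitochondrion",
                      contours = list(square_contour(1000))))
    if (n_ves > 0) objs <- c(objs, list(list(label = "vesicle",
                                             contours = ves)))
    contour_scene(objs, scale = 1)
  }
  m <- vesicles_per_micron(mk_scene(8))
  expect_equal(m$perimeter, 4)
  expect_equal(m$vesicles_per_micron, 2)
  expect_equal(vesicles_per_micron(mk_scene(0))$vesicles_per_micron, 0)
  sc <- gen_em_scene(12, 30, 5, capture_fraction = 0.5,
                     cfg = synth_config(seed = 62))
  expect_equal(vesicles_per_micron(sc)$n_vesicles, 12)
})

test_that("decorated_fraction matches the tangent-disc closed form", {
  # straight edge decorated by one 30-nm vesicle tangent to it, dilation
  # 15 nm: covered length = chord of a 30-nm-radius disc centered 15 nm
  # off the line = 2*sqrt(30^2 - 15^2)
  side <- 4000
  mito <- square_contour(side, pts_per_edge = 40)
  ves <- regular_polygon(15, 256, cx = 0, cy = -side / 2 - 15)
  sc <- contour_scene(list(
    list(label = "mitochondrion", contours = list(mito)),
    list(label = "vesicle", contours = list(ves))), scale = 1)
  frac <- decorated_fraction(sc, dilation = 15)$decorated_fraction
  covered_nm <- frac * 4 * side
  expect_lt(abs(covered_nm - 2 * sqrt(30^2 - 15^2)) /
              (2 * sqrt(30^2 - 15^2)), 0.02)
  # and against the fine-grained sampling oracle
  oracle <- invquant:::decorated_fraction_sampled(sc, 15, step_nm = 0.5)
  expect_lt(abs(frac - oracle) / oracle, 0.02)
  # vesicle ring tightly enclosing the mitochondrion: fraction 1
  ring <- regular_polygon(4000, 128)
  sc2 <- contour_scene(list(
    list(label = "mitochondrion", contours = list(square_contour(1000))),
    list(label = "vesicle", contours = list(ring))), scale = 1)
  expect_equal(decorated_fraction(sc2, 15)$decorated_fraction, 1)
})

test_that("decorated_fraction properties hold on synthetic scenes", {
  sc <- gen_em_scene(15, 30, 6, capture_fraction = 0.7,
                     cfg = synth_config(seed = 63))
  f5 <- decorated_fraction(sc, 5)$decorated_fraction
  f10 <- decorated_fraction(sc, 10)$decorated_fraction
  f15 <- decorated_fraction(sc, 15)$decorated_fraction
  expect_lte(f5, f10)
  expect_lte(f10, f15)
  expect_gte(f5, 0)
  expect_lte(f15, 1)
  # rigid motion invariance and scale equivariance
  rotate_scene <- function(scene, ang, dx, dy) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    scene$objects <- lapply(scene$objects, function(ob) {
      ob$contours <- lapply(ob$contours, function(ct) {
        xy <- ct[, 1:2] %*% t(R)
        cbind(x = xy[, 1] + dx, y = xy[, 2] + dy, z = ct[, 3])
      })
      ob
    })
    scene
  }
  scr <- rotate_scene(sc, 0.7, 123.4, -55.6)
  expect_equal(decorated_fraction(scr, 15)$decorated_fraction, f15,
               tolerance = 1e-9)
  expect_equal(mito_perimeter(scr), mito_perimeter(sc), tolerance = 1e-9)
  # halving the pixel scale with doubled coordinates: identical nm results
  sc_half <- sc
  sc_half$scale <- sc$scale / 2
  sc_half$objects <- lapply(sc$objects, function(ob) {
    ob$contours <- lapply(ob$contours, function(ct) {
      cbind(x = 2 * ct[, 1], y = 2 * ct[, 2], z = ct[, 3])
    })
    ob
  })
  expect_equal(decorated_fraction(sc_half, 15)$decorated_fraction, f15,
               tolerance = 1e-9)
})

test_that("exact and sampled decorated fractions agree on random scenes", {
  for (s in 1:3) {
    sc <- gen_em_scene(12, 30, 8, capture_fraction = 0.5,
                       mito_shape = list(r_nm = 300),
                       cfg = synth_config(seed = 70 + s))
    exact <- decorated_fraction(sc, 15)$decorated_fraction
    oracle <- invquant:::decorated_fraction_sampled(sc, 15, 0.5)
    expect_lt(abs(exact - oracle) / oracle, 0.02)
  }
})

test_that("em_analyze recovers generator ground truth end to end", {
  sc <- gen_em_scene(30, 30, 9.4, capture_fraction = 0.6,
                     cfg = synth_config(seed = 64))
  res <- em_analyze(sc, micrograph_id = "m1")
  gt <- ground_truth(sc)$vesicles
  expect_equal(nrow(res$vesicles), 30)
  expect_lt(max(abs(sort(res$vesicles$diameter_nm) -
                      sort(gt$diameter_nm))), 1e-6)
  expect_equal(res$micrograph$n_vesicles, 30)
  expect_gt(res$micrograph$decorated_fraction, 0)
})
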