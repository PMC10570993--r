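model_xyz <- function(m) as.matrix(m$nodes[, c("x", "y", "z")])

test_that("sides split into CS, NS and interpolated sandwiched bands", {
  m <- assemble(tworing_bands(), 8)
  s <- split_sides(m)
  expect_true(s$applicable)
  expect_equal(s$sides$side, c("CS", "NS"))
  expect_equal(s$sides$w, c(1, 0))

  m3 <- assemble(threering_bands(), 8)
  s3 <- split_sides(m3)
  expect_equal(s3$sides$side, c("CS", "sandwiched", "NS"))
  expect_equal(s3$sides$w[2], 0.5)

  # single subcomplex: axial variability inapplicable, not fatal
  m1 <- assemble(select_labels(
    make_synthetic_ru(z = c(25, 20), r = c(50, 52), alpha = c(0, 0),
                      subcomplex = c("CR", "CR")),
    label_selection("SynNup")), 8)
  expect_false(split_sides(m1)$applicable)
  expect_error(measure_height(m1), "one subcomplex")
  expect_error(measure_twist(m1), "one subcomplex")
  expect_warning(m1b <- set_height(m1, 30), "not applied")
  expect_identical(m1b$nodes, m1$nodes)
})

test_that("set_height rescales z to the target CS-NS difference", {
  m <- assemble(tworing_bands(), 8) # CS at +25, NS at -25
  expect_equal(measure_height(m), 50)
  # identity at the current height
  m_same <- set_height(m, 50)
  expect_equal(model_xyz(m_same), model_xyz(m), tolerance = 1e-12)
  m30 <- set_height(m, 30)
  expect_equal(mean(m30$nodes$z[m30$nodes$band == 1]), 15)
  expect_equal(mean(m30$nodes$z[m30$nodes$band == 2]), -15)
  expect_equal(measure_height(m30), 30)
  # x, y untouched; sandwiched bands move by their weight
  expect_identical(m30$nodes$x, m$nodes$x)
  m3 <- set_height(assemble(threering_bands(), 8), 25)
  expect_equal(mean(m3$nodes$z[m3$nodes$band == 2]), 0) # w = 0.5, centred
  expect_error(set_height(m, -1), "> 0")
})

test_that("twist is set exactly, measured back, and rotation-invariant", {
  m <- assemble(tworing_bands(), 8)
  expect_equal(measure_twist(m), 0, tolerance = 1e-12)
  theta <- 14 * pi / 180
  mt <- set_twist(m, theta)
  expect_equal(measure_twist(mt), theta, tolerance = 1e-9)
  # radii and z unchanged (pure rotation)
  expect_equal(sqrt(mt$nodes$x^2 + mt$nodes$y^2),
               sqrt(m$nodes$x^2 + m$nodes$y^2), tolerance = 1e-12)
  expect_identical(mt$nodes$z, m$nodes$z)
  # identity when theta equals the current twist
  mt2 <- set_twist(mt, theta)
  expect_equal(model_xyz(mt2), model_xyz(mt), tolerance = 1e-9)
  # invariance under global rotation about z
  rot <- mt
  a <- 0.7
  x <- rot$nodes$x; y <- rot$nodes$y
  rot$nodes$x <- cos(a) * x - sin(a) * y
  rot$nodes$y <- sin(a) * x + cos(a) * y
  expect_equal(measure_twist(rot), theta, tolerance = 1e-9)
  # parameter recovery across a sweep of angles, incl. wrap-sensitive ones
  for (th in c(-0.5, 0.3, 9.6 * pi / 180, 3)) {
    expect_equal(measure_twist(set_twist(m, th)), th, tolerance = 1e-9)
  }
})

test_that("tilt is a rigid per-side rotation with vMF-distributed axes", {
  m <- assemble(tworing_bands(), 8)
  # very large concentration: no visible tilt (mean polar angle is about
  # sqrt(pi / (2 kappa)) ~ 1.3e-4 rad, i.e. ~0.01 nm at radius 54)
  m_still <- with_seed(5, apply_tilt(m, 1e8))
  expect_lt(max(abs(model_xyz(m_still) - model_xyz(m))), 0.05)
  # rigidity: pairwise within-side distances preserved
  mt <- with_seed(7, apply_tilt(m, 20))
  for (b in 1:2) {
    d0 <- dist(model_xyz(m)[m$nodes$band == b, ])
    d1 <- dist(model_xyz(mt)[mt$nodes$band == b, ])
    expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  }
  expect_error(apply_tilt(m, 0), "kappa")

  # mean resultant length of vMF draws matches the closed form
  kappa <- 50
  dirs <- with_seed(11, rvmf_z(1e4, kappa))
  rbar <- sqrt(sum(colMeans(dirs)^2))
  expected <- 1 / tanh(kappa) - 1 / kappa
  expect_lt(abs(rbar - expected), 4 * 1 / sqrt(1e4 * kappa))
})

test_that("shift translates sides laterally with the configured SD", {
  m <- assemble(tworing_bands(), 8)
  expect_identical(model_xyz(apply_shift(m, 0)), model_xyz(m))
  n_rep <- 2000
  dx_cs <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    ms <- with_seed(1000 + i, apply_shift(m, 3))
    expect_identical(ms$nodes$z, m$nodes$z) # z untouched
    dx_cs[i] <- mean(ms$nodes$x[ms$nodes$band == 1]) -
      mean(m$nodes$x[m$nodes$band == 1])
  }
  # empirical SD of the per-side x offset close to 3 (4 sigma MC band)
  expect_lt(abs(sd(dx_cs) - 3), 4 * 3 / sqrt(2 * (n_rep - 1)))
})

test_that("radius scaling is isotropic and lateral-only", {
  m <- assemble(tworing_bands(), 8)
  expect_equal(model_xyz(set_mean_radius(m, mean_radius(m))),
               model_xyz(m), tolerance = 1e-12)
  m2 <- set_mean_radius(m, 2 * mean_radius(m))
  expect_equal(sqrt(m2$nodes$x^2 + m2$nodes$y^2),
               2 * sqrt(m$nodes$x^2 + m$nodes$y^2))
  expect_identical(m2$nodes$z, m$nodes$z)
  # pairwise lateral distances scale by the same factor
  d0 <- dist(cbind(m$nodes$x, m$nodes$y))
  d2 <- dist(cbind(m2$nodes$x, m2$nodes$y))
  expect_equal(as.numeric(d2), 2 * as.numeric(d0), tolerance = 1e-9)
  expect_error(set_mean_radius(m, -5), "> 0")
})

test_that("symmetry change keeps arc spacing and band radius offsets", {
  b <- select_labels(make_synthetic_ru(z = c(10, -10), r = c(50, 56),
                                       alpha = c(0, 0),
                                       subcomplex = c("CR", "NR")),
                     label_selection("SynNup"))
  expect_identical(change_symmetry(b, 8, s = 8), b)
  b9 <- change_symmetry(b, 9, s = 8)
  # arc length between adjacent spokes is conserved:
  # 2 pi rbar_new / 9 == 2 pi rbar / 8
  expect_equal(2 * pi * mean(b9$r) / 9, 2 * pi * mean(b$r) / 8,
               tolerance = 1e-12)
  # band offsets from the mean radius preserved
  expect_equal(b9$r - mean(b9$r), b$r - mean(b$r))
  expect_identical(b9$z, b$z)
  # 9-fold models have a strictly greater fitted radius
  r8 <- npc_features(assemble(b, 8), with_ellipse = FALSE)$npc$radius
  r9 <- npc_features(assemble(b9, 9), with_ellipse = FALSE)$npc$radius
  expect_gt(r9, r8)
  expect_error(change_symmetry(b, 2), "s_new")
})

test_that("per-NPC parameter draws follow N(X, sd^2)", {
  expect_identical(draw_parameter(10, 0), 10)
  expect_error(draw_parameter(10, -1), "sd")
  draws <- with_seed(13, replicate(1e5, draw_parameter(10, 2)))
  expect_lt(abs(mean(draws) - 10), 4 * 2 / sqrt(1e5))
  expect_lt(abs(sd(draws) - 2), 4 * 2 / sqrt(2 * 1e5))
})

test_that("elongation forces vanish at q = 1 and produce graded ellipticity", {
  m <- assemble(tworing_bands(), 8)
  expect_identical(elongation_forces(m, 1), rep(0, 16))
  expect_error(elongation_forces(m, 0), "q must")
  expect_error(elongation_forces(m, 1.2), "q must")

  # fitted axis ratio decreases monotonically with q (population means)
  bands <- tworing_bands()
  mean_ratio <- function(q) {
    cfg <- simulation_config(dmag = 0, q = q, seed = 31, n_npcs = 40)
    mean(vapply(0:39, function(i) {
      mm <- simulate_npc(bands, cfg, index = i)
      xyz <- model_xyz(mm)
      mean(vapply(1:2, function(b) {
        fit_ellipse_3d(xyz[mm$nodes$band == b, , drop = FALSE])$ratio
      }, numeric(1)))
    }, numeric(1)))
  }
  r_by_q <- vapply(c(1, 0.9, 0.8), mean_ratio, numeric(1))
  expect_equal(r_by_q[1], 1, tolerance = 1e-6)
  expect_gt(r_by_q[1], r_by_q[2])
  expect_gt(r_by_q[2], r_by_q[3])
  # calibration contract: q = 0.8 relaxes to a ratio within 5%
  expect_lt(abs(r_by_q[3] - 0.8), 0.05 * 0.8)
})

test_that("elongation orientation is uniform on the circle", {
  ru1 <- make_synthetic_ru(z = 0, r = 53.7, alpha = 0, subcomplex = "CR")
  bands <- select_labels(ru1, label_selection("SynNup"))
  cfg <- simulation_config(dmag = 0, q = 0.7, seed = 17, n_npcs = 400)
  phis <- vapply(0:399, function(i) {
    mm <- simulate_npc(bands, cfg, index = i)
    ax <- fit_ellipse_3d(model_xyz(mm))$major_axis
    atan2(ax[2], ax[1])
  }, numeric(1))
  # Rayleigh test on doubled angles (orientation is pi-periodic)
  a2 <- 2 * phis
  n <- length(a2)
  rbar <- sqrt(mean(cos(a2))^2 + mean(sin(a2))^2)
  p_value <- exp(-n * rbar^2)
  expect_gt(p_value, 0.01)
})

test_that("nodes of distinct bands never coincide under the class presets", {
  bands <- tworing_bands()
  for (preset in names(npc_class_presets())) {
    args <- npc_class_presets()[[preset]]
    args$dmag <- 15
    args$seed <- 23
    args$n_npcs <- 2
    cfg <- do.call(simulation_config, args)
    for (i in 0:1) {
      mm <- simulate_npc(bands, cfg, index = i)
      expect_gt(min(dist(model_xyz(mm))), 0.1)
    }
  }
})
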