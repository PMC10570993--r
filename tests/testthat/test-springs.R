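ring_xy <- function(n = 8, r = 50) {
  th <- 2 * pi * (0:(n - 1)) / n
  cbind(r * cos(th), r * sin(th))
}

test_that("spring layout matches the neighbour order and stiffness ordering", {
  spr <- build_springs(ring_xy(), h = 2)
  expect_equal(nrow(spr$radial), 8)
  expect_equal(nrow(spr$circ), 16) # s * h distinct springs for h < s/2
  # every node has exactly 2h = 4 circumferential neighbours
  deg <- table(c(spr$circ$i, spr$circ$j))
  expect_true(all(deg == 4))
  # shorter springs are stiffer; radial springs weakest
  k1 <- spr$circ$k[spr$circ$order == 1]
  k2 <- spr$circ$k[spr$circ$order == 2]
  expect_lt(diff(range(k1)), 1e-9 * mean(k1))
  expect_gt(min(k1), max(k2))
  expect_gt(min(k2), spr$radial$k[1])

  spr0 <- build_springs(ring_xy(), h = 0)
  expect_null(spr0$circ)
  expect_error(build_springs(ring_xy(), h = 5), "h must")
  # h = s/2 springs are deduplicated (i+4 pairs counted once)
  spr4 <- build_springs(ring_xy(), h = 4)
  expect_equal(nrow(spr4$circ), 8 * 4 - 4)
})

test_that("force covariance is an RBF kernel on radius-equalized distances", {
  xyz <- cbind(c(40, 60), c(0, 0), c(0, 0)) # same angle, radii 40 and 60
  cv <- force_covariance(xyz, dmag = 9, sigma = 25)
  expect_equal(diag(cv), rep(9, 2), ignore_attr = TRUE) # (dmag/3)^2 diag
  # equalized positions coincide -> full covariance
  expect_equal(cv[1, 2], 9)

  expect_equal(force_covariance(xyz, dmag = 0, sigma = 25),
               matrix(0, 2, 2), ignore_attr = TRUE)
  expect_error(force_covariance(xyz, dmag = -1), "dmag")

  # entries decrease monotonically with equalized distance
  xyz8 <- cbind(ring_xy(8, 50), 0)
  cv8 <- force_covariance(xyz8, dmag = 9, sigma = 25)
  expect_true(all(diff(cv8[1, 2:5]) < 0))
})

test_that("sampled scalar forces realize the configured covariance", {
  xyz <- cbind(ring_xy(6, 50), 0)
  cv <- force_covariance(xyz, dmag = 10, sigma = 25)
  expect_identical(sample_scalar_forces(cv * 0), rep(0, 6))
  n_draw <- 1e4
  draws <- with_seed(3, {
    t(replicate(n_draw, sample_scalar_forces(cv)))
  })
  # marginal SD = dmag / 3 at every node
  se_sd <- (10 / 3) / sqrt(2 * n_draw)
  expect_true(all(abs(apply(draws, 2, sd) - 10 / 3) < 5 * se_sd))
  # entrywise covariance agreement within 5 standard errors
  emp <- cov(draws)
  se <- sqrt((outer(diag(cv), diag(cv)) + cv^2) / n_draw)
  expect_true(all(abs(emp - cv) < 5 * se))
  # ~99.7% of scalars fall within +-dmag (3 sigma)
  frac <- mean(abs(draws) <= 10)
  expect_lt(abs(frac - 0.9973), 0.003)
})

test_that("radialization yields planar, radial, torque-free force vectors", {
  expect_equal(radialize(2, matrix(c(1, 0, 5), 1)), cbind(2, 0, 0),
               ignore_attr = TRUE)
  expect_equal(radialize(0, matrix(c(3, 4, 0), 1)), cbind(0, 0, 0),
               ignore_attr = TRUE)
  xyz <- cbind(ring_xy(8, 50), 1:8)
  f <- with_seed(9, rnorm(8, 0, 5))
  fv <- radialize(f, xyz)
  expect_true(all(fv[, 3] == 0))
  torque <- sum(xyz[, 1] * fv[, 2] - xyz[, 2] * fv[, 1])
  expect_lt(abs(torque), 1e-9)
  expect_error(radialize(1, matrix(c(0, 0, 1), 1)), "central axis")
})

test_that("relaxation reproduces closed-form and symmetry oracles", {
  # rest state is already the equilibrium
  spr <- build_springs(ring_xy(), h = 2)
  eq0 <- relax(spr, rep(0, 8))
  expect_equal(unclass(eq0), ring_xy(), tolerance = 1e-9,
               ignore_attr = TRUE)

  # closed form: radial springs only, uniform outward force f -> dr = f/k_r
  spr0 <- build_springs(ring_xy(), h = 0)
  f <- 2.5
  eq <- relax(spr0, rep(f, 8))
  expect_equal(sqrt(rowSums(eq^2)), rep(50 + f / spr0$radial$k[1], 8),
               tolerance = 1e-8)
  expect_lt(attr(eq, "residual"), 1e-6)

  # 8-fold symmetric forces give an 8-fold symmetric equilibrium
  spr2 <- build_springs(ring_xy(), h = 2)
  eq2 <- relax(spr2, rep(c(4, -3), 4))
  r2 <- sqrt(rowSums(eq2^2))
  expect_equal(r2[1:2], r2[3:4], tolerance = 1e-6)
  expect_equal(r2[1:2], r2[7:8], tolerance = 1e-6)

  # vector-force input is projected on the rest radial directions
  fv <- radialize(rep(f, 8), cbind(ring_xy(), 0))
  eqv <- relax(spr0, fv[, 1:2])
  expect_equal(unclass(eqv), unclass(eq), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("deformation is deterministic, local and monotone in dmag", {
  bands <- tworing_bands()
  cfg <- function(dm) simulation_config(dmag = dm, seed = 19, n_npcs = 1)

  # dmag = 0 leaves the model untouched
  m0 <- assemble(bands, 8)
  md <- deform_npc(m0, dmag = 0, omag = 0)
  expect_equal(as.matrix(md$nodes[, c("x", "y", "z")]),
               as.matrix(m0$nodes[, c("x", "y", "z")]), tolerance = 1e-12)

  # same seed -> bit-identical, different seed -> different
  a <- simulate_npc(bands, cfg(10), index = 3L)
  b <- simulate_npc(bands, cfg(10), index = 3L)
  expect_identical(a$nodes, b$nodes)
  c2 <- simulate_npc(bands, cfg(10), index = 4L)
  expect_false(identical(a$nodes, c2$nodes))

  # equilibrium residual below tolerance on every simulation
  expect_lt(a$provenance$relax_residual, 1e-6)

  # mean node displacement strictly increases with dmag
  base <- as.matrix(assemble(bands, 8)$nodes[, c("x", "y", "z")])
  mean_disp <- function(dm) {
    mean(vapply(0:49, function(i) {
      m <- deform_npc(assemble(bands, 8), dmag = dm, omag = 0,
                      seed = 19, index = i)
      mean(sqrt(rowSums((as.matrix(m$nodes[, c("x", "y", "z")]) - base)^2)))
    }, numeric(1)))
  }
  disps <- vapply(c(1, 5, 10, 20), mean_disp, numeric(1))
  expect_true(all(diff(disps) > 0))

  # no inter-node overlap across 100 seeds at strong deformation
  min_d <- vapply(0:99, function(i) {
    m <- deform_npc(assemble(bands, 8), dmag = 20, omag = 10,
                    seed = 19, index = i)
    min(dist(as.matrix(m$nodes[, c("x", "y", "z")])))
  }, numeric(1))
  expect_gt(min(min_d), 0)

  # concentricity: adjacent (nearly coplanar) bands share their center
  # shift because radius equalization makes their force fields coincide
  near <- select_labels(make_synthetic_ru(z = c(2, -2), r = c(50, 56),
                                          alpha = c(0, 0),
                                          subcomplex = c("CR", "NR")),
                        label_selection("SynNup"))
  base_n <- as.matrix(assemble(near, 8)$nodes[, c("x", "y", "z")])
  cdist <- numeric(50)
  disp <- numeric(50)
  for (i in 0:49) {
    m <- deform_npc(assemble(near, 8), dmag = 10, omag = 0,
                    seed = 19, index = i)
    xyz <- as.matrix(m$nodes[, c("x", "y", "z")])
    c1 <- fit_circle_3d(xyz[m$nodes$band == 1, ])$center
    c2 <- fit_circle_3d(xyz[m$nodes$band == 2, ])$center
    cdist[i + 1] <- sqrt(sum((c1[1:2] - c2[1:2])^2))
    disp[i + 1] <- mean(sqrt(rowSums((xyz - base_n)^2)))
  }
  expect_lt(mean(cdist), 0.5 * mean(disp))
})

test_that("axial offsets are correlated, additive and lateral-preserving", {
  bands <- tworing_bands()
  m0 <- assemble(bands, 8)
  xyz <- as.matrix(m0$nodes[, c("x", "y", "z")])
  expect_identical(with_seed(2, sample_axial_offsets(xyz, 0)), rep(0, 16))
  m <- deform_npc(m0, dmag = 0, omag = 8, seed = 5, index = 0)
  expect_identical(m$nodes$x, m0$nodes$x)
  expect_identical(m$nodes$y, m0$nodes$y)
  expect_false(identical(m$nodes$z, m0$nodes$z))
  # marginal SD of offsets is omag / 3
  draws <- with_seed(4, replicate(4000, sample_axial_offsets(xyz, 6)[1]))
  expect_lt(abs(sd(draws) - 2), 5 * 2 / sqrt(2 * 4000))
})
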