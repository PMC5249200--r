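test_that("cup geometry carries the analytic shell volume and validates", {
  s <- make_cup_geometry(cup_spec(32, 50))
  expect_equal(s$analytic_volume, 2 * pi / 3 * (25^3 - 16^3))
  expect_error(cup_spec(32, 32), "outer_diameter")
  expect_error(cup_spec(-1, 50), "inner_diameter")
  expect_error(cup_spec(32, 50, density = 0), "density")
  # the inner void is not material; the shell is; outside is not
  expect_false(solid_inside(s, c(0, 0, 0)))
  expect_true(solid_inside(s, c(0, 0, 20.5)))
  expect_false(solid_inside(s, c(0, 0, -20.5)))  # below the rim plane
  expect_false(solid_inside(s, c(0, 0, 26)))
})

test_that("wear only removes material and is monotone in penetration", {
  s <- make_cup_geometry(std_cup)
  p0 <- wear_pattern(0)
  expect_equal(true_wear_volume(std_cup, p0), 0)
  w0 <- apply_wear(s, p0)
  # zero penetration with the head equal to the inner sphere is an identity
  set.seed(11)
  pts <- matrix(runif(300, -26, 26), ncol = 3)
  expect_identical(solid_inside(w0, pts), solid_inside(s, pts))
  # worn solid is a subset of the unworn solid
  w <- apply_wear(s, wear_pattern(0.8))
  inw <- solid_inside(w, pts)
  expect_true(all(!inw | solid_inside(s, pts)))
  # deficit grows with penetration
  d <- c(0.1, 0.2, 0.4, 0.8)
  v <- vapply(d, function(x) true_wear_volume(std_cup, wear_pattern(x)),
              numeric(1))
  expect_true(all(diff(v) > 0))
  # penetration through the shell is rejected
  expect_error(apply_wear(s, wear_pattern(9.5)), "through the cup shell")
})

test_that("independent wear-volume oracles agree with each other and the closed form", {
  pat <- wear_pattern(0.5)
  v_grid <- true_wear_volume(std_cup, pat, method = "grid")
  v_mc <- true_wear_volume(std_cup, pat, method = "mc", seed = 7)
  # lens-shaped deficit of two equal spheres has a closed form
  r <- 16; d <- 0.5
  v_closed <- 4 / 3 * pi * r^3 - pi / 12 * (4 * r + d) * (2 * r - d)^2
  expect_equal(v_grid, v_closed, tolerance = 1e-6)
  expect_lt(abs(v_mc - v_grid) / v_grid, 1e-3)
  # oblique load direction: quadrature vs Monte-Carlo
  pat2 <- wear_pattern(0.4, load_direction = c(0.15, -0.1, 1))
  g2 <- true_wear_volume(std_cup, pat2, method = "grid")
  m2 <- true_wear_volume(std_cup, pat2, method = "mc", seed = 3)
  expect_lt(abs(m2 - g2) / g2, 1e-3)
})

test_that("voxelization recovers analytic volume and is seed-deterministic", {
  s <- sphere_solid(5)
  v <- voxelize(s, voxel_size = 0.2)
  expect_equal(ctwear:::gray_weighted_volume(v), 4 / 3 * pi * 125,
               tolerance = 0.01)
  # blur 0, noise 0 on a solid-covered grid: constant material level
  cube <- voxelize(sphere_solid(50),
                   voxel_size = 0.5, blur_sigma = 0,
                   grid = list(dims = c(8, 8, 8), origin = c(-2, -2, -2)))
  expect_true(all(cube$grid == 100))
  # same seed, identical volumes; different seed differs
  a <- voxelize(s, voxel_size = 0.4, noise_sd = 5, seed = 42)
  b <- voxelize(s, voxel_size = 0.4, noise_sd = 5, seed = 42)
  c <- voxelize(s, voxel_size = 0.4, noise_sd = 5, seed = 43)
  expect_identical(a$grid, b$grid)
  expect_false(identical(a$grid, c$grid))
})

test_that("voxelized volume estimate converges quadratically with voxel size", {
  s <- sphere_solid(5)
  va <- 4 / 3 * pi * 125
  hs <- c(1.25, 0.5, 0.2)
  errs <- vapply(hs, function(h)
    abs(ctwear:::gray_weighted_volume(voxelize(s, voxel_size = h)) - va) / va,
    numeric(1))
  # the gray-weighted estimator is essentially unbiased, so its error sits
  # on a quantization-noise floor that shrinks ~ h^2 rather than falling
  # strictly between any two particular resolutions
  expect_true(all(errs <= 0.02 * hs^2))
  expect_lt(errs[3], 0.001)
})

test_that("simulated weight series matches the linear model exactly without noise", {
  ws <- simulate_weight_series(rate = 5.1, soak_amplitude = 0, balance_sd = 0,
                               cycles = seq(0, 2, by = 0.4), seed = 1)
  losses <- ws$weights[1] - ws$weights
  expect_equal(losses, c(0, 2.04, 4.08, 6.12, 8.16, 10.2))
  # zero rate, zero noise: constant weight
  ws0 <- simulate_weight_series(rate = 0, soak_amplitude = 0, balance_sd = 0,
                                seed = 1)
  expect_equal(diff(ws0$weights), rep(0, 5))
  expect_error(simulate_weight_series(rate = -1), "rate")
  # deterministic given seed
  w1 <- simulate_weight_series(5, seed = 9)
  w2 <- simulate_weight_series(5, seed = 9)
  expect_identical(w1$weights, w2$weights)
})
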