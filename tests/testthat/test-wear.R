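test_that("self-registration returns the identity with near-zero RMS", {
  m <- coarse_cup_meshes()$before
  tf <- register_surfaces(m, m, exclusion = NULL, n_samples = 1500)
  expect_lt(tf$rms, 1e-6)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-6)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-6)
})

test_that("registration recovers a known perturbation of the worn mesh", {
  cm <- coarse_cup_meshes()
  tf_true <- rigid_transform(rotation_matrix(c(0, 1, 0), 4), c(1.5, -0.8, 0.6))
  moved <- apply_transform(tf_true, cm$after)
  excl <- calotte_exclusion(radius = 21.5, center = tf_true$translation)
  tf <- register_surfaces(cm$before, moved, exclusion = excl)
  # the composed transform must fix the cup surface (modulo the pole-axis
  # symmetry of the backside): measure residual as surface distance
  comp <- compose_transform(tf, tf_true)
  idx <- round(seq(1, nrow(cm$after$vertices), length.out = 1500))
  p2 <- apply_transform(comp, cm$after$vertices[idx, ])
  cc <- ctwear:::mesh_closest_cpp(p2, cm$after$vertices, cm$after$triangles)
  voxel <- coarse_cup_volumes()$voxel
  expect_lt(sqrt(mean(cc$dist^2)) / voxel, 0.15)
  expect_lt(tf$rms / voxel, 0.15)
})

test_that("exclusion predicates must leave enough sample points", {
  m <- coarse_cup_meshes()$before
  all_out <- function(v) rep(TRUE, nrow(v))
  expect_error(register_surfaces(m, m, exclusion = all_out),
               "sample points")
})

test_that("wear volume differencing matches truth and rigid invariance", {
  cm <- coarse_cup_meshes()
  cv <- coarse_cup_volumes()
  expect_equal(wear_volume(cm$before, cm$before), 0)
  truth <- true_wear_volume(std_cup, cv$pattern)
  dv <- wear_volume(cm$before, cm$after)
  expect_equal(dv, truth, tolerance = 0.02)
  # a common rigid motion of both states changes dV by < 0.5%
  tf <- rigid_transform(rotation_matrix(c(1, 2, 0.5), 17), c(3, -2, 5))
  dv2 <- wear_volume(apply_transform(tf, cm$before),
                     apply_transform(tf, cm$after))
  expect_lt(abs(dv2 - dv) / dv, 0.005)
  # swapped states are negative wear and warn
  expect_warning(wear_volume(cm$after, cm$before), "negative")
})

test_that("mass conversion is exact at both published densities", {
  expect_identical(mass_from_volume(10, 0.934), 9.34)
  expect_identical(mass_from_volume(10, 0.945), 9.45)
  expect_identical(mass_from_volume(0, 0.934), 0)
  dv <- 123.4567
  expect_identical(mass_from_volume(dv, 0.934) / dv, 0.934)
  expect_error(mass_from_volume(10, 0), "density")
  expect_identical(density_preset("conversion"), 0.934)
  expect_identical(density_preset("tabulated"), 0.945)
})

test_that("wear map localizes the scar and integrates to the wear volume", {
  cm <- coarse_cup_meshes()
  cv <- coarse_cup_volumes()
  region <- articular_region()
  # identical states: all deviations are exactly zero
  wm0 <- wear_map(cm$before, cm$before, region = region, search = 1)
  expect_true(all(abs(wm0$deviation_mm) < 1e-12, na.rm = TRUE))
  wm <- wear_map(cm$before, cm$after, region = region, search = 2)
  s <- attr(wm, "summary")
  # maximum loss approximates the penetration depth within one voxel
  d <- cv$pattern$penetration_depth
  expect_lt(abs(-s$min_deviation_mm - d), cv$voxel)
  # the deepest vertex sits at the scar center (the cup pole)
  deepest <- wm[which.min(wm$deviation_mm), ]
  expect_lt(sqrt(deepest$x^2 + deepest$y^2), 3)
  expect_gt(deepest$z, 14)
  # area-weighted integral of the deviation field reproduces dV within 5%
  dv <- wear_volume(cm$before, cm$after)
  expect_equal(s$volume_integral_mm3, dv, tolerance = 0.05)
})

test_that("quantify_wear composes the chain and flags negative wear", {
  cm <- coarse_cup_meshes()
  res <- quantify_wear(cm$before, cm$after, density = 0.934,
                       register = FALSE)
  expect_s3_class(res, "wear_result")
  expect_identical(res$delta_mass_mg, res$delta_volume_mm3 * 0.934)
  expect_false(res$negative_wear)
  expect_warning(
    rev_res <- quantify_wear(cm$after, cm$before, register = FALSE),
    "negative")
  expect_true(rev_res$negative_wear)
})

test_that("rigid transforms compose, invert and validate", {
  tf <- rigid_transform(rotation_matrix(c(1, 1, 0), 30), c(1, 2, 3))
  inv <- invert_transform(tf)
  comp <- compose_transform(inv, tf)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-12)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-12)
  set.seed(2)
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_transform(inv, apply_transform(tf, p)), p,
               tolerance = 1e-12)
  expect_error(rigid_transform(diag(3) * 2), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "orthonormal")
})
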