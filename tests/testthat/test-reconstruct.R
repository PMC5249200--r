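disk_volume <- function(n = 64, radius = 20, level = 100, slices = 2) {
  xy <- (0:(n - 1)) - (n - 1) / 2
  rr <- sqrt(outer(xy^2, xy^2, "+"))
  g <- array(ifelse(rr <= radius, level, 0), dim = c(n, n, slices))
  voxel_volume(g, voxel_size = 1)
}

test_that("forward projection is zero-preserving, symmetric and linear", {
  zero <- voxel_volume(array(0, c(32, 32, 2)), 1)
  expect_true(all(forward_project(zero, 10)$data == 0))
  # a centered disk projects to an angle-independent profile
  sino <- forward_project(disk_volume(), 12)
  prof <- sino$data[, , 1]
  dev <- max(abs(sweep(prof, 2, colMeans(prof))))
  # bilinear resampling jitters the sharp disk edge by a few percent
  expect_lt(dev / max(prof), 0.03)
  # linearity: P(a + b) = P(a) + P(b)
  set.seed(5)
  a <- voxel_volume(array(runif(32 * 32 * 2), c(32, 32, 2)), 1)
  b <- voxel_volume(array(runif(32 * 32 * 2), c(32, 32, 2)), 1)
  ab <- voxel_volume(a$grid + b$grid, 1)
  expect_equal(forward_project(ab, 7)$data,
               forward_project(a, 7)$data + forward_project(b, 7)$data,
               tolerance = 1e-12)
  expect_error(forward_project(disk_volume(), 0), "n_angles")
  expect_error(forward_project(voxel_volume(array(0, c(16, 8, 4)), 1), 4),
               "square")
})

test_that("filtered back-projection round-trips a disk phantom", {
  zero_sino <- sinogram(array(0, c(10, 32, 2)), (0:9) * pi / 10, 1)
  expect_true(all(fbp_reconstruct(zero_sino)$grid == 0))
  vol <- disk_volume()
  rec <- fbp_reconstruct(forward_project(vol, 90), "ramp")
  xy <- (0:63) - 31.5
  mask <- array(sqrt(outer(xy^2, xy^2, "+")) <= 29, dim = dim(vol$grid))
  expect_lt(volume_nrmse(rec, vol, mask), 0.08)
  # hann is gentler than ramp, still a valid reconstruction
  rec_h <- fbp_reconstruct(forward_project(vol, 90), "hann")
  expect_lt(volume_nrmse(rec_h, vol, mask), 0.12)
  expect_error(fbp_reconstruct(forward_project(vol, 90), "shepp"),
               "arg")
})

test_that("round-trip error decreases monotonically with angle count", {
  vol <- disk_volume()
  xy <- (0:63) - 31.5
  mask <- array(sqrt(outer(xy^2, xy^2, "+")) <= 29, dim = dim(vol$grid))
  errs <- vapply(c(20, 45, 90), function(na)
    volume_nrmse(fbp_reconstruct(forward_project(vol, na)), vol, mask),
    numeric(1))
  expect_true(all(diff(errs) < 0))
})
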