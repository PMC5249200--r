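make_bimodal_volume <- function(lo, hi, noise_sd = 0, seed = 1) {
  set.seed(seed)
  g <- array(rep(c(lo, hi), each = 4000) +
               rnorm(8000, sd = noise_sd), dim = c(20, 20, 20))
  voxel_volume(g, voxel_size = 1)
}

test_that("ISO-50 threshold is the midpoint of the two histogram modes", {
  expect_equal(iso50_threshold(make_bimodal_volume(0, 100)), 50)
  expect_equal(iso50_threshold(make_bimodal_volume(20, 80)), 50)
  # noisy two-mode histogram stays within 2 gray units of the clean answer
  th <- iso50_threshold(make_bimodal_volume(0, 100, noise_sd = 5, seed = 42))
  expect_lt(abs(th - 50), 2)
  # unimodal input cannot be separated
  flat <- voxel_volume(array(rnorm(8000, 50, 1), dim = c(20, 20, 20)), 1)
  expect_error(iso50_threshold(flat), "cannot separate material")
})

test_that("extracted sphere surface volume is within 1% of the analytic value", {
  v <- voxelize(sphere_solid(5), voxel_size = 0.2)
  m <- extract_surface(v)
  expect_true(is_closed_mesh(m))
  expect_equal(m$enclosed_volume, 4 / 3 * pi * 125, tolerance = 0.01)
  # gray-weighted voxel counting is an independent estimator of the same
  # quantity; they must agree within twice a single-voxel surface shell
  shell <- 4 * pi * 25 * v$voxel_size
  expect_lt(abs(m$enclosed_volume - ctwear:::gray_weighted_volume(v)),
            2 * shell)
})

test_that("adaptive refinement off reproduces the pure iso-surface", {
  v <- voxelize(sphere_solid(4), voxel_size = 0.4)
  m1 <- extract_surface(v, threshold = 50, adaptive = FALSE)
  m2 <- extract_surface(v, threshold = 50, adaptive = FALSE)
  expect_identical(m1$vertices, m2$vertices)
  m3 <- extract_surface(v, threshold = 50, adaptive = TRUE)
  expect_identical(m1$triangles, m3$triangles)  # connectivity unchanged
  expect_false(identical(m1$vertices, m3$vertices))
})

test_that("adaptive refinement beats a global threshold under a shading field", {
  v <- voxelize(sphere_solid(5), voxel_size = 0.2)
  d <- dim(v$grid)
  xi <- (seq_len(d[1]) - 1) / (d[1] - 1)
  # additive cupping-like shading lifts background and material together,
  # so the local surface level varies ~20% of the contrast across the field
  v$grid <- v$grid + array(rep(20 * xi, times = d[2] * d[3]), dim = d)
  va <- 4 / 3 * pi * 125
  th <- iso50_threshold(v)
  err_glob <- abs(extract_surface(v, th, adaptive = FALSE)$enclosed_volume - va)
  err_adap <- abs(extract_surface(v, th, adaptive = TRUE)$enclosed_volume - va)
  expect_lte(err_adap, err_glob)
})

test_that("surface volume estimate converges with voxel size on a sphere", {
  va <- 4 / 3 * pi * 125
  errs <- vapply(c(0.5, 0.3, 0.2), function(h)
    abs(extract_surface(voxelize(sphere_solid(5), voxel_size = h),
                        threshold = 50)$enclosed_volume - va) / va,
    numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})

test_that("mesh volume: cube, icosphere convergence, orientation invariance", {
  cube <- unit_cube_mesh()
  expect_equal(cube$enclosed_volume, 1)
  # refined icospheres approach (4/3) pi monotonically from below
  errs <- vapply(1:3, function(s)
    abs(icosphere(1, s)$enclosed_volume - 4 * pi / 3), numeric(1))
  expect_true(all(diff(errs) < 0))
  # flipping orientation leaves the reported volume unchanged
  flipped <- cube
  flipped$triangles <- flipped$triangles[, c(1, 3, 2)]
  expect_equal(mesh_volume(flipped), 1)
  # open meshes are rejected
  open_mesh <- cube
  open_mesh$triangles <- open_mesh$triangles[-1, ]
  expect_error(mesh_volume(open_mesh), "closed")
  expect_error(extract_surface(voxel_volume(array(0, c(4, 4, 4)), 1),
                               threshold = 50), "strictly between")
})

test_that("MPE utility implements (9 + L/50) um with its pass predicate", {
  expect_identical(mpe_length(50), 10)
  expect_identical(mpe_length(0), 9)
  expect_identical(mpe_length(100), 11)
  expect_true(mpe_check(9.9, 50))
  expect_false(mpe_check(-10.1, 50))
  expect_error(mpe_length(-1), "L must be")
})
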