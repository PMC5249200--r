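#' Gray-value voxel volume
#'
#' The CT image model: a 3-D array of gray values with an isotropic physical
#' voxel size and the world position of the center of voxel `[1, 1, 1]`
#' (voxel-center convention).  All lengths are in mm.
#'
#' @param grid 3-D numeric array of gray values (each dimension >= 2).
#' @param voxel_size Isotropic voxel edge length, mm (default 0.031, i.e.
#'   31 um).
#' @param origin World position of the center of the first voxel, mm.
#' @param metadata Free-form named list carried along (acquisition settings,
#'   generator parameters, ...).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(grid, voxel_size = 0.031, origin = c(0, 0, 0),
                         metadata = list()) {
  if (!is.array(grid) || length(dim(grid)) != 3 || any(dim(grid) < 2))
    stop_validation("grid must be a 3-D array with all dimensions >= 2")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop_validation("voxel_size must be a positive scalar (mm)")
  if (length(origin) != 3 || !all(is.finite(origin)))
    stop_validation("origin must be a finite 3-vector (mm)")
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin), metadata = metadata),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("voxel_volume: %d x %d x %d voxels, %g mm/voxel, gray [%g, %g]\n",
              d[1], d[2], d[3], x$voxel_size,
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Acquisition settings (metadata only)
#'
#' Scanner settings carried as metadata on generated volumes; only
#' `n_projections` has computational meaning (it sizes the sinogram in the
#' reconstruction stage).  X-ray physics is not simulated.
#'
#' @param n_projections Number of projections over 180 degrees (default 1500).
#' @param voltage_kV,current_uA,integration_ms,temperature_C Stored metadata.
#' @return A named list of class `acquisition_config`.
#' @export
acquisition_config <- function(n_projections = 1500, voltage_kV = 194,
                               current_uA = 46, integration_ms = 1415,
                               temperature_C = 20) {
  if (!is.numeric(n_projections) || n_projections < 1)
    stop_validation("n_projections must be >= 1")
  structure(list(n_projections = as.integer(n_projections),
                 voltage_kV = voltage_kV, current_uA = current_uA,
                 integration_ms = integration_ms,
                 temperature_C = temperature_C),
            class = "acquisition_config")
}

# default sampling grid for a solid: bbox plus a margin wide enough that
# blur tails decay to background before the boundary.  The lattice is
# offset by an incommensurate fraction of a voxel so that flat solid faces
# can never coincide exactly with voxel-center or subsample planes (exact
# coincidence makes tie-breaking of boundary samples systematic).
default_grid <- function(solid, voxel_size, blur_sigma) {
  bb <- solid_bbox(solid)
  margin <- 4 * blur_sigma + 2 * voxel_size
  lo <- bb[1, ] - margin + (sqrt(2) - 1.25) * voxel_size
  hi <- bb[2, ] + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_size)) + 2L)
  list(dims = dims, origin = lo)
}

#' Voxelize an implicit solid into a CT-like gray-value volume
#'
#' Emulates a reconstructed micro-CT image of the solid: per-voxel material
#' occupancy is computed by supersampling, scaled to the material gray
#' level, blurred with an isotropic Gaussian (partial-volume / system blur),
#' and optionally degraded with additive Gaussian gray noise.  The result is
#' deterministic for a given seed.
#'
#' @param solid A `ct_solid`.
#' @param voxel_size Voxel edge length, mm.  The hardware default is
#'   0.031 mm; desk-scale phantoms typically use 0.15-0.3 mm.
#' @param blur_sigma Gaussian blur standard deviation, mm (default: one
#'   voxel).
#' @param noise_sd Additive Gaussian noise standard deviation, gray units.
#' @param seed RNG seed for the noise (required for reproducibility when
#'   `noise_sd > 0`).
#' @param grid Optional sampling grid `list(dims, origin)`; default covers
#'   the solid with a blur-safe margin.
#' @param supersample Occupancy supersampling factor per axis (default 3,
#'   i.e. 27 samples per voxel).
#' @param material_level Gray level of solid material (background is 0);
#'   fixed default 100.
#' @return A [voxel_volume()].
#' @export
voxelize <- function(solid, voxel_size = 0.031, blur_sigma = voxel_size,
                     noise_sd = 0, seed = NULL, grid = NULL,
                     supersample = 3, material_level = 100) {
  stopifnot(inherits(solid, "ct_solid"))
  if (voxel_size <= 0) stop_validation("voxel_size must be positive")
  if (is.null(grid)) grid <- default_grid(solid, voxel_size, blur_sigma)
  dims <- as.integer(grid$dims)
  origin <- as.numeric(grid$origin)
  occ <- cup_occupancy_cpp(dims, rep(voxel_size, 3), origin,
                           as.integer(supersample),
                           solid$r_in, solid$r_out,
                           solid$plane_n, solid$plane_off,
                           solid$sub_spheres,
                           as.numeric(t(solid$rotation)), solid$translation)
  g <- occ * material_level
  if (blur_sigma > 0)
    g <- gauss_blur3_cpp(g, dims, blur_sigma / voxel_size)
  if (noise_sd > 0)
    g <- with_seed(seed, g + rnorm(length(g), sd = noise_sd))
  voxel_volume(array(g, dim = dims), voxel_size, origin,
               metadata = list(blur_sigma_mm = blur_sigma,
                               noise_sd = noise_sd, seed = seed,
                               supersample = supersample,
                               material_level = material_level))
}

#' Add seeded Gaussian gray noise to a volume
#'
#' Convenience for studying noise sensitivity without recomputing the
#' (expensive, deterministic) occupancy and blur of [voxelize()].
#'
#' @param volume A [voxel_volume()].
#' @param sd Noise standard deviation, gray units.
#' @param seed RNG seed.
#' @return A new [voxel_volume()].
#' @export
add_gray_noise <- function(volume, sd, seed = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (sd < 0) stop_validation("sd must be >= 0")
  if (sd == 0) return(volume)
  volume$grid <- with_seed(seed, volume$grid +
    array(rnorm(length(volume$grid), sd = sd), dim = dim(volume$grid)))
  volume$metadata$noise_sd <- sd
  volume$metadata$seed <- seed
  volume
}

# gray-value-weighted volume estimate (voxel counting); kept as an
# independent test oracle against the mesh-based estimator
gray_weighted_volume <- function(volume, material_level = 100) {
  sum(volume$grid) / material_level * volume$voxel_size^3
}

#' Simulate a gravimetric weighing campaign
#'
#' Generates the cumulative weighings of a wearing specimen together with
#' its paired soak-control cup.  The specimen loses mass linearly with
#' cycles at `rate` while both cups gain fluid following a saturating
#' exponential soak term \eqn{c\,(1 - e^{-t/\tau})}; each reported weight is
#' the mean of `n_weighings` independent balance readings with standard
#' deviation `balance_sd`.
#'
#' @param rate True wear rate, mg/Mc (>= 0).
#' @param soak_amplitude Saturating soak mass gain, mg (default 1).
#' @param soak_tau Soak time constant, Mc (default 0.5).
#' @param balance_sd Single-reading balance standard deviation, mg
#'   (default 0.01, a 0.01 mg balance).
#' @param n_weighings Readings averaged per stop (default 3, triplicate).
#' @param cycles Cycle grid in Mc, strictly increasing from 0 (default
#'   `seq(0, 2, by = 0.4)`).
#' @param initial_weight Specimen start weight, mg.
#' @param seed RNG seed; the series is deterministic given the seed.
#' @param specimen_id,material Identifiers carried on the result.
#' @return A [weight_series()].
#' @export
simulate_weight_series <- function(rate, soak_amplitude = 1, soak_tau = 0.5,
                                   balance_sd = 0.01, n_weighings = 3,
                                   cycles = seq(0, 2, by = 0.4),
                                   initial_weight = 30000, seed = NULL,
                                   specimen_id = "sim", material = "other") {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate < 0)
    stop_validation("rate must be >= 0 (mg/Mc)")
  if (cycles[1] != 0 || any(diff(cycles) <= 0))
    stop_validation("cycles must be strictly increasing and start at 0")
  soak <- soak_amplitude * (1 - exp(-cycles / soak_tau))
  with_seed(seed, {
    read_mean <- function(true_w)
      vapply(true_w, function(w)
        mean(w + rnorm(n_weighings, sd = balance_sd)), numeric(1))
    w_spec <- read_mean(initial_weight - rate * cycles + soak)
    w_ctrl <- read_mean(initial_weight + soak)
    weight_series(specimen_id = specimen_id, material = material,
                  cycles = cycles, weights = w_spec,
                  control_weights = w_ctrl)
  })
}
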