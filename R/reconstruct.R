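# Desk-scale CT stage: parallel-beam forward projection and filtered
# back-projection, so the measurement chain can be exercised from
# projections rather than from voxelized phantoms.  Parallel geometry with
# angles uniform over [0, pi) stands in for the instrument's cone beam; the
# reconstruction step of the real workflow is otherwise a black box.

#' Parallel-beam sinogram
#'
#' @param data Array `n_angles x n_detector x n_slices` of line integrals.
#' @param angles Projection angles in radians, uniform over `[0, pi)`.
#' @param detector_spacing Detector bin spacing, mm.
#' @param voxel_size,origin Reconstruction grid geometry carried through
#'   for the round trip.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(data, angles, detector_spacing, voxel_size = 1,
                     origin = c(0, 0, 0)) {
  if (length(dim(data)) == 2) data <- array(data, dim = c(dim(data), 1))
  if (length(dim(data)) != 3)
    stop_validation("sinogram data must be (angles x detector x slices)")
  if (dim(data)[1] != length(angles))
    stop_validation("angle count must match first data dimension")
  if (detector_spacing <= 0) stop_validation("detector_spacing must be > 0")
  structure(list(data = data, angles = angles,
                 detector_spacing = detector_spacing,
                 voxel_size = voxel_size, origin = origin),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("sinogram: %d angles x %d bins x %d slices, spacing %g mm\n",
              d[1], d[2], d[3], x$detector_spacing))
  invisible(x)
}

# bilinear sample of a 2-D image at fractional indices (1-based), 0 outside
interp2_zero <- function(img, xi, yi) {
  n1 <- nrow(img); n2 <- ncol(img)
  out <- numeric(length(xi))
  ok <- xi >= 1 & xi <= n1 & yi >= 1 & yi <= n2
  x <- xi[ok]; y <- yi[ok]
  i0 <- pmin(floor(x), n1 - 1); j0 <- pmin(floor(y), n2 - 1)
  fx <- x - i0; fy <- y - j0
  idx <- function(i, j) img[cbind(i, j)]
  v <- idx(i0, j0) * (1 - fx) * (1 - fy) + idx(i0 + 1, j0) * fx * (1 - fy) +
    idx(i0, j0 + 1) * (1 - fx) * fy + idx(i0 + 1, j0 + 1) * fx * fy
  out[ok] <- v
  out
}

#' Parallel-beam forward projection
#'
#' Slice-wise line integrals of the gray values along parallel rays for
#' `n_angles` uniformly spaced angles over 180 degrees.  Linear in the
#' input volume.
#'
#' @param volume A [voxel_volume()] with square axial slices.
#' @param n_angles Number of projection angles (>= 1); the hardware default
#'   would be 1500, desk-scale tests use far fewer.
#' @return A [sinogram()] (line integrals in gray-value x mm).
#' @export
forward_project <- function(volume, n_angles) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (n_angles < 1) stop_validation("n_angles must be >= 1")
  d <- dim(volume$grid)
  if (d[1] != d[2])
    stop_validation("axial slices must be square for parallel projection")
  n <- d[1]
  nz <- d[3]
  angles <- (seq_len(n_angles) - 1) * pi / n_angles
  ctr <- (n - 1) / 2
  u <- seq_len(n) - 1 - ctr      # integration steps along the ray
  s <- seq_len(n) - 1 - ctr      # detector bin offsets
  out <- array(0, dim = c(n_angles, n, nz))
  for (a in seq_len(n_angles)) {
    ca <- cos(angles[a]); sa <- sin(angles[a])
    X <- outer(u, s, function(ui, sj) sj * ca - ui * sa) + ctr + 1
    Y <- outer(u, s, function(ui, sj) sj * sa + ui * ca) + ctr + 1
    for (k in seq_len(nz)) {
      M <- matrix(interp2_zero(volume$grid[, , k], as.vector(X),
                               as.vector(Y)), n, n)
      out[a, , k] <- colSums(M) * volume$voxel_size
    }
  }
  sinogram(out, angles, detector_spacing = volume$voxel_size,
           voxel_size = volume$voxel_size, origin = volume$origin)
}

# frequency response of the discrete ramp (Ram-Lak) filter, built from its
# exact band-limited spatial kernel to avoid the DC bias of |f| sampling
ramp_filter <- function(m) {
  h <- numeric(m)
  h[1] <- 0.25
  j <- seq(1, m / 2, by = 2)
  h[1 + j] <- -1 / (pi^2 * j^2)
  h[m + 1 - j] <- -1 / (pi^2 * j^2)
  2 * Re(fft(h))
}

#' Filtered back-projection reconstruction
#'
#' Slice-wise parallel-beam FBP with the exact discrete ramp (Ram-Lak)
#' filter, optionally apodized with a Hann window for noisy data.  The
#' output grid matches the grid the sinogram was projected from.
#'
#' @param sino A [sinogram()] with >= 2 angles.
#' @param filter `"ramp"` (default) or `"hann"`.
#' @return A [voxel_volume()].
#' @export
fbp_reconstruct <- function(sino, filter = c("ramp", "hann")) {
  filter <- match.arg(filter)
  stopifnot(inherits(sino, "sinogram"))
  d <- dim(sino$data)
  n_angles <- d[1]; n <- d[2]; nz <- d[3]
  if (n_angles < 2) stop_validation("need at least 2 angles")
  m <- 2^ceiling(log2(max(64, 2 * n)))
  filt <- ramp_filter(m)
  if (filter == "hann") {
    k <- 0:(m - 1)
    filt <- filt * 0.5 * (1 + cos(2 * pi * pmin(k, m - k) / m))
  }
  ctr <- (n - 1) / 2
  xc <- matrix(rep(seq_len(n) - 1 - ctr, n), n, n)         # x varies by row
  yc <- t(xc)
  out <- array(0, dim = c(n, n, nz))
  for (k in seq_len(nz)) {
    P <- sino$data[, , k] / sino$detector_spacing  # line integrals, px units
    Ppad <- rbind(t(P), matrix(0, m - n, n_angles))
    Q <- Re(mvfft(mvfft(Ppad) * filt, inverse = TRUE)) / m
    acc <- matrix(0, n, n)
    for (a in seq_len(n_angles)) {
      t_idx <- xc * cos(sino$angles[a]) + yc * sin(sino$angles[a]) + ctr + 1
      q <- Q[seq_len(n), a]
      i0 <- floor(t_idx)
      fr <- t_idx - i0
      inside <- i0 >= 1 & i0 <= n - 1
      v <- matrix(0, n, n)
      v[inside] <- q[i0[inside]] * (1 - fr[inside]) +
        q[i0[inside] + 1] * fr[inside]
      acc <- acc + v
    }
    out[, , k] <- acc * pi / (2 * n_angles)
  }
  voxel_volume(out, sino$voxel_size, sino$origin,
               metadata = list(filter = filter, n_angles = n_angles))
}

#' Normalized RMS error between two volumes
#'
#' RMSE divided by the gray-value range of the reference, evaluated inside
#' an optional mask (e.g. the reconstruction circle).
#'
#' @param estimate,reference `voxel_volume` objects on the same grid.
#' @param mask Optional logical array selecting the evaluation region.
#' @return NRMSE as a fraction (0.05 = 5%).
#' @export
volume_nrmse <- function(estimate, reference, mask = NULL) {
  a <- estimate$grid; b <- reference$grid
  if (!all(dim(a) == dim(b))) stop_validation("grids differ in size")
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  sqrt(mean((a[mask] - b[mask])^2)) / diff(range(b[mask]))
}
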