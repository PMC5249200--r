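#' Triangle surface model
#'
#' A closed, consistently oriented triangle mesh with vertices in world
#' coordinates (mm).  Created by [extract_surface()] or directly from
#' vertex/triangle arrays; carries its enclosed volume.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param check If `TRUE` (default), verify the mesh is closed and
#'   consistently oriented.
#' @return An object of class `surface_model` with element
#'   `enclosed_volume` (mm^3).
#' @export
surface_model <- function(vertices, triangles, check = TRUE) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3 || ncol(triangles) != 3)
    stop_validation("vertices and triangles must have 3 columns")
  if (nrow(triangles) < 4) stop_validation("mesh has too few triangles")
  if (max(triangles) > nrow(vertices) || min(triangles) < 1)
    stop_validation("triangle indices out of range")
  m <- structure(list(vertices = vertices, triangles = triangles,
                      enclosed_volume = NA_real_),
                 class = "surface_model")
  if (check && !is_closed_mesh(m))
    stop_validation("mesh is not closed and consistently oriented")
  m$enclosed_volume <- mesh_volume(m, check_closed = FALSE)
  m
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("surface_model: %d vertices, %d triangles, enclosed volume %.4f mm^3\n",
              nrow(x$vertices), nrow(x$triangles), x$enclosed_volume))
  invisible(x)
}

#' Is a mesh closed and consistently oriented?
#'
#' A watertight 2-manifold mesh has every undirected edge shared by exactly
#' two triangles, and consistent orientation means each directed edge
#' appears exactly once.
#'
#' @param mesh A `surface_model` (or a list with `vertices`/`triangles`).
#' @return Logical.
#' @export
is_closed_mesh <- function(mesh) {
  tr <- mesh$triangles
  a <- c(tr[, 1], tr[, 2], tr[, 3])
  b <- c(tr[, 2], tr[, 3], tr[, 1])
  dir_key <- a * 2^26 + b
  if (anyDuplicated(dir_key) > 0) return(FALSE)
  und_key <- pmin(a, b) * 2^26 + pmax(a, b)
  k <- sort(und_key)
  n <- length(k)
  if (n %% 2 != 0) return(FALSE)
  all(k[seq(1, n, by = 2)] == k[seq(2, n, by = 2)])
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra
#' spanned by the origin and each triangle); the absolute value is returned
#' so the result does not depend on whether normals point inward or
#' outward.
#'
#' @param mesh A `surface_model`.
#' @param check_closed Verify closedness first (default `TRUE`); an open
#'   mesh is an error because the divergence theorem does not apply.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh, check_closed = TRUE) {
  if (check_closed && !is_closed_mesh(mesh))
    stop_validation("mesh_volume requires a closed mesh")
  v <- mesh$vertices
  tr <- mesh$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  s <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
    p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(s)) / 6
}

# per-triangle (un-normalized) normals and areas
mesh_face_normals <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Outward vertex normals of a mesh
#'
#' Area-weighted average of incident face normals, normalized, with the
#' global sign fixed so normals point out of the enclosed material.
#'
#' @param mesh A `surface_model`.
#' @return n x 3 matrix of unit normals (rows of `NA` where degenerate).
#' @export
mesh_vertex_normals <- function(mesh) {
  fn <- mesh_face_normals(mesh)
  tr <- mesh$triangles
  idx <- c(tr[, 1], tr[, 2], tr[, 3])
  acc <- rowsum(rbind(fn, fn, fn), group = idx)
  out <- matrix(0, nrow(mesh$vertices), 3)
  out[as.integer(rownames(acc)), ] <- acc
  nrm <- sqrt(rowSums(out^2))
  out <- out / ifelse(nrm > 0, nrm, NA_real_)
  # orient outward: signed volume with current orientation must be positive
  v <- mesh$vertices
  s <- sum(v[tr[, 1], 1] * fn[, 1] + v[tr[, 1], 2] * fn[, 2] +
             v[tr[, 1], 3] * fn[, 3])
  if (s < 0) out <- -out
  out
}

# per-vertex area: one third of incident triangle areas
mesh_vertex_areas <- function(mesh) {
  fn <- mesh_face_normals(mesh)
  area <- sqrt(rowSums(fn^2)) / 2
  tr <- mesh$triangles
  idx <- c(tr[, 1], tr[, 2], tr[, 3])
  acc <- rowsum(rep(area / 3, 3), group = idx)
  out <- numeric(nrow(mesh$vertices))
  out[as.integer(rownames(acc))] <- acc
  out
}

#' ISO-50 global surface threshold
#'
#' Estimates the surface gray threshold as the midpoint of the two dominant
#' modes of the gray-value histogram (background and material peaks) — the
#' standard starting value that adaptive local methods subsequently refine.
#' Peak locations are sharpened by parabolic interpolation on a smoothed
#' histogram.
#'
#' @param volume A [voxel_volume()].
#' @param bins Number of histogram bins (default 256).
#' @param smooth_sd Gaussian smoothing of the histogram counts, in bins
#'   (default 2).
#' @return The threshold gray value.
#' @export
iso50_threshold <- function(volume, bins = 256, smooth_sd = 2) {
  stopifnot(inherits(volume, "voxel_volume"))
  g <- as.vector(volume$grid)
  rng <- range(g)
  if (diff(rng) <= 0) stop_validation("cannot separate material: constant volume")
  brks <- seq(rng[1], rng[2], length.out = bins + 1)
  centers <- (brks[-1] + brks[-(bins + 1)]) / 2
  counts <- tabulate(pmin(pmax(findInterval(g, brks, all.inside = TRUE), 1L),
                          bins), nbins = bins)
  # smooth with a fixed Gaussian kernel
  rad <- max(1L, as.integer(ceiling(3 * smooth_sd)))
  ker <- exp(-0.5 * ((-rad):rad)^2 / smooth_sd^2)
  ker <- ker / sum(ker)
  padded <- c(rep(0, rad), counts, rep(0, rad))
  sm <- vapply(seq_len(bins), function(i)
    sum(padded[i:(i + 2 * rad)] * ker), numeric(1))
  # local maxima of the smoothed histogram
  is_max <- c(FALSE, sm[2:(bins - 1)] > sm[1:(bins - 2)] &
                sm[2:(bins - 1)] >= sm[3:bins], FALSE)
  is_max[1] <- sm[1] > sm[2]
  is_max[bins] <- sm[bins] > sm[bins - 1]
  peaks <- which(is_max)
  if (length(peaks) < 2)
    stop_validation("cannot separate material: histogram is unimodal")
  # dominant mode, then the highest mode at least a quarter-range away
  # (modes broadened by shading must not be picked twice), and the two
  # must be separated by a genuine valley
  p1 <- peaks[which.max(sm[peaks])]
  far <- peaks[abs(peaks - p1) >= bins / 4]
  if (length(far) < 1)
    stop_validation("cannot separate material: histogram is unimodal")
  p2 <- far[which.max(sm[far])]
  valley <- min(sm[min(p1, p2):max(p1, p2)])
  if (valley > 0.5 * min(sm[p1], sm[p2]))
    stop_validation("cannot separate material: histogram is unimodal")
  peaks <- c(p1, p2)
  refine <- function(i) {
    if (i <= 1 || i >= bins) return(centers[i])
    y0 <- sm[i - 1]; y1 <- sm[i]; y2 <- sm[i + 1]
    den <- y0 - 2 * y1 + y2
    off <- if (abs(den) < 1e-12) 0 else 0.5 * (y0 - y2) / den
    centers[i] + off * (centers[2] - centers[1])
  }
  mean(c(refine(peaks[1]), refine(peaks[2])))
}

#' Determine the material surface from a gray-value volume
#'
#' Extracts the iso-surface at the given threshold with sub-voxel linear
#' interpolation (marching tetrahedra on a 6-tet cube decomposition).  With
#' `adaptive = TRUE` each vertex is then relocated along the local
#' gray-gradient direction to the 50% crossing between locally estimated
#' background and material levels (robust 10th/90th percentiles within
#' `window` voxels each side), which removes the bias of a single global
#' threshold when gray levels vary across the field.
#'
#' @param volume A [voxel_volume()].
#' @param threshold Surface gray value; `NULL` (default) uses
#'   [iso50_threshold()].  Must lie strictly between the volume min and max.
#' @param adaptive Apply adaptive local refinement (default `TRUE`).
#' @param window Half-width of the local sampling window along the
#'   gradient, voxels (default 5).
#' @return A [surface_model()] (closed; error if the iso-surface is clipped
#'   by the grid boundary).
#' @export
extract_surface <- function(volume, threshold = NULL, adaptive = TRUE,
                            window = 5) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (is.null(threshold)) threshold <- iso50_threshold(volume)
  rng <- range(volume$grid)
  if (threshold <= rng[1] || threshold >= rng[2])
    stop_validation("threshold must lie strictly between the gray min and max")
  dims <- dim(volume$grid)
  mt <- marching_tets_cpp(as.vector(volume$grid), dims, threshold,
                          rep(volume$voxel_size, 3), volume$origin)
  if (nrow(mt$vertices) == 0)
    stop_validation("no surface found at the given threshold")
  if (adaptive) {
    mt$vertices <- adaptive_relocate_cpp(mt$vertices, as.vector(volume$grid),
                                         dims, rep(volume$voxel_size, 3),
                                         volume$origin, as.integer(window),
                                         0.1, 0.9, 0.5)
  }
  m <- structure(list(vertices = mt$vertices, triangles = mt$triangles,
                      enclosed_volume = NA_real_),
                 class = "surface_model")
  if (!is_closed_mesh(m))
    stop_validation("extracted mesh is open (surface touches the grid boundary)")
  m$enclosed_volume <- mesh_volume(m, check_closed = FALSE)
  m
}

#' Maximum permissible length-measurement error of the CT system
#'
#' The metrological CT system's stated maximum permissible error (MPE) for
#' length measurements, \eqn{(9 + L/50)\,\mu m} with `L` in mm.
#'
#' @param L Measured length, mm (>= 0).
#' @return MPE in micrometres.
#' @export
#' @examples
#' mpe_length(50)  # 10 um
mpe_length <- function(L) {
  if (any(!is.finite(L)) || any(L < 0))
    stop_validation("L must be >= 0 (mm)")
  9 + L / 50
}

#' Does a length error pass the MPE specification?
#'
#' @param error_um Observed length error, micrometres (signed).
#' @param L Measured length, mm.
#' @return Logical: `TRUE` when `|error_um| <= mpe_length(L)`.
#' @export
mpe_check <- function(error_um, L) {
  abs(error_um) <= mpe_length(L)
}

#' Refined icosahedral sphere mesh
#'
#' Analytic test mesh: subdivided icosahedron projected to a sphere.  Used
#' to verify mesh volume convergence toward \eqn{(4/3)\pi r^3}.
#'
#' @param radius Sphere radius, mm.
#' @param subdivisions Number of 4-to-1 triangle subdivisions (default 2).
#' @param center Sphere center.
#' @return A [surface_model()].
#' @export
icosphere <- function(radius = 1, subdivisions = 2, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- get0(key, envir = edge_mid)
      if (!is.null(id)) return(id)
      p <- (v[a, ] + v[b, ])
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1]] <<- p
      id <- nv + length(newv)
      assign(key, id, envir = edge_mid)
      id
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  v <- sweep(v * radius, 2, -as.numeric(center))
  surface_model(v, f)
}
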