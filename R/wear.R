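#' Exclude the articular calotte from registration sampling
#'
#' Returns a predicate marking vertices near the cup's inner (articulating)
#' surface, where wear changes the geometry.  Registration must be driven
#' by the unchanged backside and rim, so these vertices are excluded from
#' the fit.
#'
#' @param radius Exclusion radius, mm: vertices closer than this to
#'   `center` are excluded.  For a cup, the midshell radius
#'   `(r_in + r_out) / 2` separates the articular surface from the
#'   backside.
#' @param center Cup center, mm.
#' @return A function mapping an n x 3 vertex matrix to a logical vector
#'   (`TRUE` = excluded).
#' @export
calotte_exclusion <- function(radius, center = c(0, 0, 0)) {
  force(radius); force(center)
  function(vertices) {
    sqrt(rowSums(sweep(rbind(vertices), 2, center)^2)) < radius
  }
}

#' Rigid registration of a moving surface onto a reference surface
#'
#' Iterative-closest-point style rigid alignment: sampled vertices of the
#' moving mesh are matched to their closest points on the reference surface
#' and the least-squares rigid transform is re-estimated (Kabsch/SVD) until
#' the point-to-surface RMS stops improving.  Vertices flagged by
#' `exclusion` (typically the worn articular calotte, see
#' [calotte_exclusion()]) never enter the fit, so wear does not bias the
#' alignment.
#'
#' @param reference,moving `surface_model` meshes (closed).
#' @param exclusion `NULL`, or a predicate on vertices (`TRUE` = exclude).
#' @param n_samples Number of moving-mesh vertices used (default 3000,
#'   deterministic evenly spaced subsample).
#' @param min_points Minimum vertices that must survive exclusion
#'   (default 1000).
#' @param max_iter,tol Iteration cap and relative RMS-change convergence
#'   tolerance; failure to converge is an error carrying the RMS trace.
#' @param tol_abs Absolute RMS-change floor, mm: changes below it
#'   (default 1e-4 mm = 0.1 um, far below the scanner's MPE) always count
#'   as converged.
#' @return A [rigid_transform()] mapping `moving` onto `reference`, with
#'   elements `rms` (final point-to-surface RMS, mm), `iterations` and
#'   `n_points`.
#' @export
register_surfaces <- function(reference, moving, exclusion = NULL,
                              n_samples = 3000, min_points = 1000,
                              max_iter = 100, tol = 1e-3, tol_abs = 1e-4) {
  stopifnot(inherits(reference, "surface_model"),
            inherits(moving, "surface_model"))
  verts <- moving$vertices
  keep <- if (is.null(exclusion)) rep(TRUE, nrow(verts)) else !exclusion(verts)
  nk <- sum(keep)
  if (nk < min_points)
    stop_validation(sprintf(
      "exclusion leaves %d sample points (< %d required)", nk, min_points))
  idx <- which(keep)[unique(round(seq(1, nk, length.out = min(n_samples, nk))))]
  p <- verts[idx, , drop = FALSE]

  R <- diag(3)
  tvec <- c(0, 0, 0)
  rms <- Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pt <- sweep(p %*% t(R), 2, -tvec)
    cc <- mesh_closest_cpp(pt, reference$vertices, reference$triangles)
    new_rms <- sqrt(mean(cc$dist^2))
    trace <- c(trace, new_rms)
    q <- cc$point
    # least-squares rigid fit p -> q (Kabsch)
    pbar <- colMeans(p)
    qbar <- colMeans(q)
    H <- crossprod(sweep(p, 2, pbar), sweep(q, 2, qbar))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    tvec <- qbar - as.vector(R %*% pbar)
    if (is.finite(rms) &&
        abs(rms - new_rms) <= tol * max(new_rms, 1e-12) + tol_abs) {
      rms <- new_rms
      converged <- TRUE
      break
    }
    rms <- new_rms
  }
  if (!converged)
    stop(sprintf(
      "registration did not converge in %d iterations (RMS trace: %s)",
      max_iter, paste(sprintf("%.5f", utils::tail(trace, 5)), collapse = ", ")))
  out <- rigid_transform(R, tvec)
  out$rms <- rms
  out$iterations <- length(trace)
  out$n_points <- nrow(p)
  out
}

#' Volumetric wear by subtraction of enclosed volumes
#'
#' \eqn{\Delta V = V_{before} - V_{after}}: the material deficit between
#' the unworn and worn closed surfaces.  Enclosed volume is invariant under
#' rigid motion, so the registration transform does not change the value;
#' it is accepted (and applied) for interface symmetry with [wear_map()].
#'
#' @param before,after `surface_model` meshes of the unworn and worn
#'   states.
#' @param transform Optional [rigid_transform()] applied to `after`.
#' @return Wear volume in mm^3.  A negative value (material apparently
#'   gained) is reported with a warning, not clipped — it signals noise or
#'   registration failure.
#' @export
wear_volume <- function(before, after, transform = NULL) {
  stopifnot(inherits(before, "surface_model"), inherits(after, "surface_model"))
  if (!is.null(transform)) after <- apply_transform(transform, after)
  dv <- mesh_volume(before) - mesh_volume(after)
  if (dv < 0)
    warning(sprintf("negative measured wear (%.4f mm^3): noise or registration failure",
                    dv))
  dv
}

#' Convert a wear volume to mass
#'
#' @param delta_volume Wear volume, mm^3.
#' @param density Material density, mg/mm^3 (see [density_preset()]).
#' @return Mass in mg (`delta_volume * density`, exact).
#' @export
#' @examples
#' mass_from_volume(10, 0.934)
mass_from_volume <- function(delta_volume, density) {
  if (!is.numeric(density) || length(density) != 1 || !is.finite(density) ||
      density <= 0)
    stop_validation("density must be positive (mg/mm^3)")
  delta_volume * density
}

#' Local wear map between unworn and worn surfaces
#'
#' For each selected vertex of the unworn surface, the signed deviation to
#' the worn surface measured along the local surface normal: negative
#' values are material loss (the retrieval-analysis convention), positive
#' values apparent gain.  Vertices whose normal ray misses the worn surface
#' within `search` mm are flagged `NA`, never silently zeroed.
#'
#' @param before,after `surface_model` meshes of the unworn and worn
#'   states.
#' @param transform Optional [rigid_transform()] applied to `after` first.
#' @param region `NULL` (all vertices) or a predicate on vertices selecting
#'   where the map is evaluated (typically the articular calotte).
#' @param search Maximum ray search distance, mm (default 2).
#' @param cutoff Deviation magnitude (mm) above which a vertex counts as
#'   worn for the patch-area summary (default 0.05).
#' @return An object of class `wear_map`: a data frame of vertex
#'   coordinates, per-vertex `deviation_mm` and `area_mm2`, with summary
#'   statistics in `attr(, "summary")` (`min_deviation_mm`,
#'   `worn_area_mm2`, `volume_integral_mm3` — the area-weighted integral of
#'   material loss, comparable to [wear_volume()] — and `n_missing`).
#' @export
wear_map <- function(before, after, transform = NULL, region = NULL,
                     search = 2, cutoff = 0.05) {
  stopifnot(inherits(before, "surface_model"), inherits(after, "surface_model"))
  if (!is.null(transform)) after <- apply_transform(transform, after)
  sel <- if (is.null(region)) rep(TRUE, nrow(before$vertices))
  else region(before$vertices)
  normals <- mesh_vertex_normals(before)
  areas <- mesh_vertex_areas(before)
  idx <- which(sel & !is.na(normals[, 1]))
  o <- before$vertices[idx, , drop = FALSE]
  d <- -normals[idx, , drop = FALSE]   # into the material
  t_hit <- mesh_raycast_cpp(o, d, after$vertices, after$triangles, search)
  deviation <- -t_hit   # worn surface deeper along the inward normal = loss
  df <- data.frame(vertex = idx, x = o[, 1], y = o[, 2], z = o[, 3],
                   deviation_mm = deviation, area_mm2 = areas[idx])
  ok <- !is.na(deviation)
  summ <- list(
    min_deviation_mm = if (any(ok)) min(deviation[ok]) else NA_real_,
    worn_area_mm2 = sum(df$area_mm2[ok & deviation < -cutoff]),
    volume_integral_mm3 = -sum(deviation[ok] * df$area_mm2[ok]),
    cutoff_mm = cutoff,
    n_vertices = length(idx),
    n_missing = sum(!ok))
  structure(df, class = c("wear_map", "data.frame"), summary = summ)
}

#' @export
print.wear_map <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("wear_map: %d vertices (%d ray misses)\n", s$n_vertices,
              s$n_missing))
  cat(sprintf("  max material loss %.4f mm; worn area (|dev| > %.2f mm) %.2f mm^2\n",
              -s$min_deviation_mm, s$cutoff_mm, s$worn_area_mm2))
  cat(sprintf("  area-integrated loss %.3f mm^3\n", s$volume_integral_mm3))
  invisible(x)
}

#' Write a wear map as CSV (vertex, deviation)
#'
#' @param map A [wear_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_wear_map_csv <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' Full wear quantification between two states
#'
#' Convenience composition of the measurement chain: surface determination
#' (for volume inputs), rigid registration with articular exclusion, volume
#' differencing, and mass conversion.
#'
#' @param before,after Unworn and worn states: `voxel_volume` or
#'   `surface_model` objects.
#' @param density Density for the mass conversion, mg/mm^3.
#' @param exclusion Registration exclusion predicate (see
#'   [calotte_exclusion()]); `NULL` registers on all vertices.
#' @param threshold,adaptive,window Surface determination settings, see
#'   [extract_surface()].
#' @param register Set `FALSE` to skip registration (already aligned
#'   states).
#' @param map Also compute a [wear_map()] (default `FALSE`).
#' @param region,search Passed to [wear_map()] when `map = TRUE`.
#' @param ... Passed to [register_surfaces()].
#' @return An object of class `wear_result`: `delta_volume_mm3`,
#'   `delta_mass_mg`, `density`, `transform`, `registration_rms_mm`,
#'   `negative_wear` flag, and optionally `map`.
#' @export
quantify_wear <- function(before, after, density = density_preset(),
                          exclusion = NULL, threshold = NULL, adaptive = TRUE,
                          window = 5, register = TRUE, map = FALSE,
                          region = NULL, search = 2, ...) {
  as_mesh <- function(x)
    if (inherits(x, "voxel_volume"))
      extract_surface(x, threshold = threshold, adaptive = adaptive,
                      window = window)
    else x
  mb <- as_mesh(before)
  ma <- as_mesh(after)
  tf <- NULL
  rms <- NA_real_
  if (register) {
    tf <- register_surfaces(mb, ma, exclusion = exclusion, ...)
    rms <- tf$rms
  }
  dv <- withCallingHandlers(
    wear_volume(mb, ma, transform = tf),
    warning = function(w) invokeRestart("muffleWarning"))
  res <- list(delta_volume_mm3 = dv,
              delta_mass_mg = mass_from_volume(dv, density),
              density = density,
              transform = tf,
              registration_rms_mm = rms,
              negative_wear = dv < 0)
  if (res$negative_wear)
    warning(sprintf("negative measured wear (%.4f mm^3)", dv))
  if (map)
    res$map <- wear_map(mb, ma, transform = tf, region = region,
                        search = search)
  structure(res, class = "wear_result")
}

#' @export
print.wear_result <- function(x, ...) {
  cat(sprintf("wear_result: dV = %.4f mm^3, dm = %.4f mg (density %g mg/mm^3)\n",
              x$delta_volume_mm3, x$delta_mass_mg, x$density))
  if (!is.na(x$registration_rms_mm))
    cat(sprintf("  registration RMS %.5f mm\n", x$registration_rms_mm))
  if (x$negative_wear) cat("  WARNING: negative measured wear\n")
  invisible(x)
}

#' Serialize a wear result to JSON
#'
#' @param result A `wear_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_wear_result_json <- function(result, path) {
  stopifnot(inherits(result, "wear_result"))
  out <- list(delta_volume_mm3 = result$delta_volume_mm3,
              delta_mass_mg = result$delta_mass_mg,
              density_mg_mm3 = result$density,
              registration_rms_mm = result$registration_rms_mm,
              negative_wear = result$negative_wear)
  if (!is.null(result$transform)) {
    out$rotation <- as.vector(result$transform$rotation)
    out$translation_mm <- result$transform$translation
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
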