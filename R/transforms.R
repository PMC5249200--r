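#' Rigid-body transform
#'
#' A proper rigid transform `x -> R x + t` (rotation `R` with det +1, no
#' scaling or reflection), used to align worn and unworn states.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation 3-vector, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop_validation("rotation must be orthonormal with det +1")
  if (length(translation) != 3 || !all(is.finite(translation)))
    stop_validation("translation must be a finite 3-vector")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("rigid_transform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  if (!is.null(x$rms))
    cat(sprintf("  registration RMS %.6f mm (%d iterations, %d points)\n",
                x$rms, x$iterations, x$n_points))
  invisible(x)
}

#' Rotation matrix about an axis
#'
#' @param axis Rotation axis (3-vector, normalized internally).
#' @param angle_deg Rotation angle in degrees.
#' @return A 3x3 rotation matrix (Rodrigues formula).
#' @export
rotation_matrix <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Apply a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @param x An n x 3 point matrix, a `surface_model`, or a `ct_solid`.
#' @return The transformed object (same type as `x`).
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "surface_model")) {
    x$vertices <- apply_transform(transform, x$vertices)
    return(x)
  }
  if (inherits(x, "ct_solid")) return(transform_solid(x, transform))
  pts <- rbind(x)
  sweep(pts %*% t(transform$rotation), 2, -transform$translation)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is the transform "apply `b`, then `a`".
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, as.vector(-Rt %*% transform$translation))
}
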