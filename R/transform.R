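#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation (3x3 orthonormal matrix with
#' determinant +1) followed by a translation in Angstroms:
#' `x -> R x + t`. It is the currency of superposition and lattice
#' propagation: Kabsch fits return one, two-fold (C2) dimer operations are
#' stored as one, and lattice placements compose them.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric translation, Angstrom.
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' t1 <- rigid_transform(diag(3), c(1, 0, 0))
#' transform_apply(t1, matrix(0, 1, 3))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation matrix is not orthonormal", call. = FALSE)
  if (det(rotation) < 0)
    stop("rotation matrix is a reflection (det < 0); only proper rotations allowed",
         call. = FALSE)
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- transform_axis_angle(x)
  cat(sprintf("<rigid_transform> angle %.2f deg, |t| = %.2f A\n",
              aa$angle_deg, vnorm(x$t)))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A `rigid_transform`.
#' @param xyz n x 3 coordinate matrix (Angstrom), or an atom tibble with
#'   `x`, `y`, `z` columns (returned with coordinates replaced).
#' @return Transformed coordinates in the same container as the input.
#' @export
transform_apply <- function(transform, xyz) {
  if (is.data.frame(xyz)) return(set_coords(xyz, transform_apply(transform, coords(xyz))))
  sweep(xyz %*% t(transform$R), 2, transform$t, `+`)
}

#' Compose two rigid transforms
#'
#' `transform_compose(a, b)` returns the transform applying `b` first, then
#' `a`: `x -> a(b(x))`.
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
transform_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param transform A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
transform_invert <- function(transform) {
  rigid_transform(t(transform$R), as.numeric(-t(transform$R) %*% transform$t))
}

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
transform_identity <- function() rigid_transform()

#' Axis-angle (screw) decomposition of a rigid transform
#'
#' Decomposes `x -> R x + t` into a rotation by `angle_deg` about an axis
#' with direction `axis` through the point `point`, plus a residual
#' translation `screw` parallel to the axis. For a crystallographic two-fold
#' the screw component is ~0 and `angle_deg` ~ 180.
#'
#' @param transform A `rigid_transform`.
#' @return List with `angle_deg`, `axis` (unit 3-vector), `point` (a point
#'   on the axis, Angstrom), `screw` (axis-parallel translation, Angstrom).
#' @export
transform_axis_angle <- function(transform) {
  R <- transform$R
  tr <- sum(diag(R))
  cos_a <- max(-1, min(1, (tr - 1) / 2))
  angle <- acos(cos_a)
  offdiag <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (angle < 1e-6 || (abs(angle - pi) > 1e-6 && vnorm(offdiag) < 1e-9)) {
    return(list(angle_deg = 0, axis = c(0, 0, 1), point = c(0, 0, 0),
                screw = transform$t))
  }
  if (abs(angle - pi) < 1e-6) {
    # axis from the dominant column of R + I
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    axis <- unit(M[, j])
  } else {
    axis <- unit(offdiag)
  }
  t_par <- sum(transform$t * axis) * axis
  t_perp <- transform$t - t_par
  # solve (I - R) p = t_perp for a point on the axis (p orthogonal component)
  A <- diag(3) - R
  # A is singular along the axis; use least squares on the perpendicular part
  p <- qr.solve(A + outer(axis, axis), t_perp)
  p <- p - sum(p * axis) * axis
  list(angle_deg = angle * 180 / pi, axis = axis, point = p, screw = t_par)
}

#' Build the two-fold (C2) rotation about a given axis
#'
#' @param axis_point point on the axis (Angstrom).
#' @param axis_direction axis direction (normalized internally).
#' @param angle_deg rotation angle in degrees (default 180).
#' @return A `rigid_transform`.
#' @export
rotation_about_axis <- function(axis_point, axis_direction, angle_deg = 180) {
  u <- unit(axis_direction)
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  p <- as.numeric(axis_point)
  rigid_transform(R, p - as.numeric(R %*% p))
}
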