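# Rotation and rigid-transform primitives. All lengths are in millimetres and
# all internal angles in radians; user-facing reports convert to degrees.

# Tolerances used across the package.
.ORTHO_TOL <- 1e-10    # per-element orthonormality check
.THETA_MIN <- 1e-8     # rad; below this a rotation counts as zero
.THETA_PI  <- 1e-6     # rad; within this of pi, use the eigenvector branch

#' Skew-symmetric (cross-product) matrix of a 3-vector
#'
#' Returns the matrix `S` such that `S %*% w == cross(v, w)` for every
#' 3-vector `w`. This is the building block of the Rodrigues rotation formula.
#'
#' @param v Numeric 3-vector.
#' @return A 3x3 antisymmetric matrix.
#' @examples
#' skew_matrix(c(0, 0, 1)) %*% c(1, 0, 0)  # == c(0, 1, 0)
#' @export
skew_matrix <- function(v) {
  stopifnot(is.numeric(v), length(v) == 3)
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), nrow = 3)
}

#' Rotation matrix from axis and angle (Rodrigues formula)
#'
#' Builds the rotation by `angle` radians about the unit vector `axis`:
#' `(1 - cos(phi)) n n^T + cos(phi) I + sin(phi) S(n)`.
#'
#' @param axis Unit 3-vector (checked to within 1e-9).
#' @param angle Rotation angle in radians.
#' @return A 3x3 orthonormal matrix with determinant +1 that fixes `axis`.
#' @examples
#' H <- rodrigues_rotation(c(0, 0, 1), pi / 2)
#' H %*% c(1, 0, 0)  # quarter turn: (0, 1, 0)
#' @export
rodrigues_rotation <- function(axis, angle) {
  stopifnot(is.numeric(axis), length(axis) == 3, is.numeric(angle),
            length(angle) == 1)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9)
    stop("`axis` must be a unit vector", call. = FALSE)
  n <- axis
  (1 - cos(angle)) * tcrossprod(n) + cos(angle) * diag(3) +
    sin(angle) * skew_matrix(n)
}

# TRUE when R is orthonormal with det +1 within tol per element.
is_rotation_matrix <- function(R, tol = .ORTHO_TOL) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

assert_rotation <- function(R, what = "rotation") {
  # registration output etc. accumulates a little float dust; validation is
  # looser than the construction tolerance but still tight
  if (!is_rotation_matrix(R, tol = 1e-8))
    stop(sprintf("`%s` must be a 3x3 orthonormal matrix with det +1", what),
         call. = FALSE)
  invisible(R)
}

#' Pose of a rigid body
#'
#' Orientation is stored as the body-frame axes expressed in the global frame,
#' column-wise; `reference_point` is a point of the body in global
#' coordinates (mm).
#'
#' @param orientation 3x3 orthonormal matrix, det +1.
#' @param reference_point Numeric 3-vector (mm). Default origin.
#' @return An object of class `body_pose`.
#' @export
body_pose <- function(orientation = diag(3), reference_point = c(0, 0, 0)) {
  assert_rotation(orientation, "orientation")
  stopifnot(length(reference_point) == 3)
  structure(list(orientation = orientation,
                 reference_point = as.numeric(reference_point)),
            class = "body_pose")
}

#' Relative rotation between two body poses
#'
#' For poses with orientation matrices `M_A` (before) and `M_B` (after), the
#' rotation carrying the body from A to B in the global frame is
#' `H = M_B %*% t(M_A)`.
#'
#' @param pose_A,pose_B [body_pose] objects (or bare 3x3 orientation
#'   matrices).
#' @return 3x3 rotation matrix `H` with `H %*% M_A == M_B`.
#' @export
relative_rotation <- function(pose_A, pose_B) {
  MA <- if (inherits(pose_A, "body_pose")) pose_A$orientation else pose_A
  MB <- if (inherits(pose_B, "body_pose")) pose_B$orientation else pose_B
  assert_rotation(MA, "pose_A orientation")
  assert_rotation(MB, "pose_B orientation")
  MB %*% t(MA)
}

#' Extract rotation angle and axis from a rotation matrix
#'
#' The angle is `acos((tr(H) - 1) / 2)`, reported in `[0, pi]`. For angles
#' away from 0 and pi the axis is the normalised vector of antisymmetric
#' elements `(H32 - H23, H13 - H31, H21 - H12) / (2 sin(phi))`; that formula
#' is singular at `sin(phi) = 0`, so near pi the axis is taken from the
#' dominant eigenvector of `(H + I) / 2`, and below the zero-rotation
#' threshold the result is flagged degenerate (the axis is meaningless).
#'
#' @param H 3x3 orthonormal matrix, det +1.
#' @return An object of class `angle_axis` with fields `angle` (radians in
#'   `[0, pi]`), `axis` (unit 3-vector) and `degenerate` (logical).
#' @export
rotation_to_angle_axis <- function(H) {
  assert_rotation(H, "H")
  cphi <- (sum(diag(H)) - 1) / 2
  phi <- acos(min(1, max(-1, cphi)))
  if (phi <= .THETA_MIN)
    return(angle_axis(0, c(1, 0, 0), degenerate = TRUE))
  if (phi >= pi - .THETA_PI) {
    # near pi: (H + I)/2 ~ n n^T; dominant eigenvector is the axis
    ev <- eigen((H + diag(3)) / 2, symmetric = TRUE)
    n <- ev$vectors[, 1]
  } else {
    n <- c(H[3, 2] - H[2, 3], H[1, 3] - H[3, 1], H[2, 1] - H[1, 2]) /
      (2 * sin(phi))
  }
  n <- n / sqrt(sum(n^2))
  # canonical sign: pick the representative whose Rodrigues matrix matches H
  if (sum((rodrigues_rotation(n, phi) - H)^2) >
      sum((rodrigues_rotation(-n, phi) - H)^2))
    n <- -n
  angle_axis(phi, n)
}

#' Angle-axis pair
#'
#' @param angle Radians in `[0, pi]`.
#' @param axis Unit 3-vector; ignored (and meaningless) when `degenerate`.
#' @param degenerate Logical; TRUE when the rotation is below the
#'   zero-rotation threshold.
#' @return Object of class `angle_axis`.
#' @export
angle_axis <- function(angle, axis, degenerate = FALSE) {
  stopifnot(angle >= 0, angle <= pi + 1e-12)
  if (!degenerate) {
    nrm <- sqrt(sum(axis^2))
    if (abs(nrm - 1) > 1e-9) stop("`axis` must be a unit vector", call. = FALSE)
    axis <- axis / nrm
  }
  structure(list(angle = as.numeric(angle), axis = as.numeric(axis),
                 degenerate = isTRUE(degenerate)),
            class = "angle_axis")
}

#' @export
print.angle_axis <- function(x, ...) {
  if (x$degenerate) {
    cat("<angle_axis> degenerate (angle ~ 0)\n")
  } else {
    cat(sprintf("<angle_axis> angle %.4f deg about (%.4f, %.4f, %.4f)\n",
                x$angle * 180 / pi, x$axis[1], x$axis[2], x$axis[3]))
  }
  invisible(x)
}

#' Rigid transform (rotation + translation)
#'
#' Acts on points as `p -> rotation %*% p + translation`.
#'
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @param translation Numeric 3-vector (mm).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  assert_rotation(rotation, "rotation")
  stopifnot(length(translation) == 3)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rotation_to_angle_axis(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              aa$angle * 180 / pi, x$translation[1], x$translation[2],
              x$translation[3]))
  invisible(x)
}

#' Transform algebra
#'
#' `compose_transform(T1, T2)` is the transform applying `T2` first, then
#' `T1`; `invert_transform` is the inverse; `apply_transform` maps one point
#' or the rows of an n x 3 matrix.
#'
#' @param T1,T2,T [rigid_transform] objects.
#' @param p Numeric 3-vector or n x 3 matrix of points (mm).
#' @return A [rigid_transform], or transformed points shaped like `p`.
#' @export
compose_transform <- function(T1, T2) {
  stopifnot(inherits(T1, "rigid_transform"), inherits(T2, "rigid_transform"))
  rigid_transform(T1$rotation %*% T2$rotation,
                  as.numeric(T1$rotation %*% T2$translation) + T1$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  Rt <- t(T$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% T$translation))
}

#' @rdname compose_transform
#' @export
apply_transform <- function(T, p) {
  stopifnot(inherits(T, "rigid_transform"))
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3)
    sweep(p %*% t(T$rotation), 2, T$translation, "+")
  } else {
    stopifnot(length(p) == 3)
    as.numeric(T$rotation %*% p) + T$translation
  }
}

#' Identity rigid transform
#' @return The identity [rigid_transform].
#' @export
identity_transform <- function() rigid_transform()

# unit-normalise a vector
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

# any unit vector orthogonal to unit vector n
orthogonal_unit <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitize(ref - sum(ref * n) * n)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
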