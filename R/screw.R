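# Finite helical (screw) axis decomposition of a rigid displacement.
#
# A displacement p -> H p + t is written as a rotation by phi about the line
# {xbar + s n} plus a translation L along n:  H (p - x) + L n = p' - x.

# Solve [(1 - cos phi) I - sin phi S(n)] x = rhs for the unique x
# perpendicular to n. The 3x3 system has n in a near-null direction, so the
# solve is done in an orthonormal basis (u, v) of the plane perpendicular to
# n, where the operator is the well-conditioned 2x2 [(1-c) s; -s (1-c)].
solve_axis_point <- function(phi, n, rhs) {
  u <- orthogonal_unit(n)
  v <- cross3(n, u)
  rhs <- rhs - sum(rhs * n) * n   # kill numerical dust along n
  cph <- cos(phi); sph <- sin(phi)
  b1 <- sum(u * rhs); b2 <- sum(v * rhs)
  det2 <- (1 - cph)^2 + sph^2     # = 2 (1 - cos phi) > 0 for phi > 0
  c1 <- ((1 - cph) * b1 - sph * b2) / det2
  c2 <- (sph * b1 + (1 - cph) * b2) / det2
  c1 * u + c2 * v
}

#' Helical (screw) axis decomposition
#'
#' Decomposes a rigid transform into a rotation by `phi` about the helical
#' axis with direction `n`, plus a translation `L` along that same axis. The
#' axis is reported by `axis_point`, the unique point on the axis
#' perpendicular to `n` from the origin (i.e. the axis point closest to the
#' origin). The translation along the axis is `L = n' t`; the axis point
#' solves `[(1 - cos phi) I - sin phi S(n)] x = t - L n` in the plane
#' perpendicular to `n`.
#'
#' When the rotation angle is below the zero-rotation threshold the motion is
#' a pure translation: `pure_translation` is set, `L` is the translation
#' magnitude and `axis` its direction (degenerate when that too vanishes).
#'
#' @param T A [rigid_transform].
#' @return Object of class `screw_decomposition` with fields `angle_axis`,
#'   `L` (mm), `axis_point` (mm, global frame) and `pure_translation`.
#' @seealso [screw_compose()] for the inverse operation,
#'   [oblique_decompose()] for the facet-axis variant.
#' @export
helical_decompose <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  aa <- rotation_to_angle_axis(T$rotation)
  t <- T$translation
  if (aa$degenerate) {
    tn <- sqrt(sum(t^2))
    if (tn < 1e-12) {
      return(structure(list(angle_axis = aa, L = 0, axis_point = c(0, 0, 0),
                            pure_translation = TRUE),
                       class = "screw_decomposition"))
    }
    return(structure(list(angle_axis = angle_axis(0, t / tn, degenerate = FALSE),
                          L = tn, axis_point = c(0, 0, 0),
                          pure_translation = TRUE),
                     class = "screw_decomposition"))
  }
  n <- aa$axis
  L <- sum(n * t)
  xbar <- solve_axis_point(aa$angle, n, t - L * n)
  structure(list(angle_axis = aa, L = L, axis_point = xbar,
                 pure_translation = FALSE),
            class = "screw_decomposition")
}

#' Rebuild a rigid transform from its helical decomposition
#'
#' Inverse of [helical_decompose()]: composes the rotation about the line
#' through `axis_point` with direction `n` and the translation `L n`, giving
#' the transform with rotation `H` and translation `(I - H) axis_point + L n`.
#' A flagged pure translation composes to a translation-only transform.
#'
#' @param d A `screw_decomposition`.
#' @return The corresponding [rigid_transform].
#' @export
screw_compose <- function(d) {
  stopifnot(inherits(d, "screw_decomposition"))
  if (d$pure_translation) {
    if (d$angle_axis$degenerate) return(identity_transform())
    return(rigid_transform(diag(3), d$L * d$angle_axis$axis))
  }
  if (d$angle_axis$degenerate)
    stop("degenerate decomposition cannot be composed", call. = FALSE)
  n <- d$angle_axis$axis
  H <- rodrigues_rotation(n, d$angle_axis$angle)
  t <- as.numeric((diag(3) - H) %*% d$axis_point) + d$L * n
  rigid_transform(H, t)
}

#' @export
print.screw_decomposition <- function(x, ...) {
  if (x$pure_translation) {
    cat(sprintf("<screw_decomposition> pure translation %.4f mm\n", x$L))
  } else {
    cat(sprintf(
      "<screw_decomposition> %.3f deg about (%.4f, %.4f, %.4f) through (%.2f, %.2f, %.2f), L = %.3f mm\n",
      x$angle_axis$angle * 180 / pi, x$angle_axis$axis[1], x$angle_axis$axis[2],
      x$angle_axis$axis[3], x$axis_point[1], x$axis_point[2], x$axis_point[3],
      x$L))
  }
  invisible(x)
}
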