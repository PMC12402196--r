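# Rotation-axis representation with translation along an arbitrary unit
# direction `a` (anatomically: the cylinder axis of the posterior talar
# facet):  H (p - x) + alpha a = p' - x.
#
# The rotation (phi, n) is identical to the helical values; only the
# translation direction and hence the axis location change. Unlike the
# helical axis, the rotation-axis location differs between the forward and
# the inverse transformation, giving a pair of parallel axes.

.EPS_COND <- 1e-3   # minimum |n . a|; below this alpha is undefined

#' Decompose a rigid transform with translation along a given direction
#'
#' Writes the transform as a rotation by `phi` about an axis with direction
#' `n` (the same angle and direction as the helical decomposition) plus a
#' translation `alpha` along the caller-supplied unit direction `a`. The
#' translation is `alpha = (n' t) / (n' a)`; the forward axis point solves
#' `[(1 - cos phi) I - sin phi S(n)] x = t - alpha a` in the plane
#' perpendicular to `n`. The inverse-transformation axis point is obtained by
#' decomposing the inverse transform with the same direction; both axis lines
#' share the direction `n` but generally sit at different locations.
#'
#' `a` is re-oriented, if needed, so that `n' a > 0`; the orientation used is
#' returned in the result, making the sign of `alpha` reproducible even
#' though a cylinder fit determines the axis only up to sign.
#'
#' @param T A [rigid_transform] whose rotation angle exceeds the
#'   zero-rotation threshold.
#' @param a Unit 3-vector, the translation direction (facet cylinder axis).
#' @return Object of class `oblique_decomposition` with fields `angle_axis`,
#'   `a` (as oriented), `alpha` (mm), `axis_point_forward`,
#'   `axis_point_inverse` (mm, global frame) and `conditioning` (`|n . a|`).
#' @seealso [oblique_compose()], [axis_pair()], [helical_decompose()]
#' @export
oblique_decompose <- function(T, a) {
  stopifnot(inherits(T, "rigid_transform"), length(a) == 3)
  if (abs(sqrt(sum(a^2)) - 1) > 1e-9)
    stop("`a` must be a unit vector", call. = FALSE)
  aa <- rotation_to_angle_axis(T$rotation)
  if (aa$degenerate)
    stop("rotation angle is below the zero-rotation threshold; ",
         "the facet-axis representation requires a rotation", call. = FALSE)
  n <- aa$axis
  cond <- abs(sum(n * a))
  if (cond <= .EPS_COND)
    stop("singular configuration: translation direction is (near) ",
         "perpendicular to the rotation axis (|n . a| <= 1e-3)", call. = FALSE)
  if (sum(n * a) < 0) a <- -a
  t <- T$translation
  alpha <- sum(n * t) / sum(n * a)
  x_fwd <- solve_axis_point(aa$angle, n, t - alpha * a)
  # inverse transformation, same physical direction a (its own canonical
  # orientation flips with n); its axis is a line in the same global frame
  Ti <- invert_transform(T)
  aai <- rotation_to_angle_axis(Ti$rotation)
  ni <- aai$axis
  ai <- if (sum(ni * a) < 0) -a else a
  alpha_i <- sum(ni * Ti$translation) / sum(ni * ai)
  x_inv <- solve_axis_point(aai$angle, ni, Ti$translation - alpha_i * ai)
  structure(list(angle_axis = aa, a = a, alpha = alpha,
                 axis_point_forward = x_fwd, axis_point_inverse = x_inv,
                 conditioning = cond),
            class = "oblique_decomposition")
}

#' Rebuild a rigid transform from an oblique decomposition
#'
#' Composes the rotation about the line through `axis_point_forward` with
#' direction `n` and the translation `alpha a`: the resulting transform has
#' rotation `H` and translation `(I - H) axis_point_forward + alpha a`.
#'
#' @param d An `oblique_decomposition` (or a list with fields `angle_axis`,
#'   `a`, `alpha`, `axis_point_forward`).
#' @return The corresponding [rigid_transform].
#' @export
oblique_compose <- function(d) {
  if (d$angle_axis$degenerate)
    stop("degenerate decomposition cannot be composed", call. = FALSE)
  n <- d$angle_axis$axis
  if (abs(sum(n * d$a)) <= .EPS_COND)
    stop("singular configuration: |n . a| <= 1e-3", call. = FALSE)
  H <- rodrigues_rotation(n, d$angle_axis$angle)
  t <- as.numeric((diag(3) - H) %*% d$axis_point_forward) + d$alpha * d$a
  rigid_transform(H, t)
}

#' Forward and inverse rotation-axis pair
#'
#' In the facet-axis representation the rotation-axis location differs
#' between the forward and the inverse transformation; the two axes are
#' parallel. This returns both axis lines and the perpendicular distance
#' between them (0 when `a` is parallel to `n`, i.e. the helical case).
#'
#' @inheritParams oblique_decompose
#' @return List with `forward` and `inverse` (each `list(point, direction)`)
#'   and `separation` (mm).
#' @export
axis_pair <- function(T, a) {
  d <- oblique_decompose(T, a)
  n <- d$angle_axis$axis
  delta <- d$axis_point_inverse - d$axis_point_forward
  delta_perp <- delta - sum(delta * n) * n
  list(forward = list(point = d$axis_point_forward, direction = n),
       inverse = list(point = d$axis_point_inverse, direction = n),
       separation = sqrt(sum(delta_perp^2)))
}

#' @export
print.oblique_decomposition <- function(x, ...) {
  cat(sprintf(
    "<oblique_decomposition> %.3f deg about (%.4f, %.4f, %.4f), alpha = %.3f mm along (%.4f, %.4f, %.4f)\n",
    x$angle_axis$angle * 180 / pi, x$angle_axis$axis[1], x$angle_axis$axis[2],
    x$angle_axis$axis[3], x$alpha, x$a[1], x$a[2], x$a[3]))
  cat(sprintf("  axis through (%.2f, %.2f, %.2f) fwd / (%.2f, %.2f, %.2f) inv, |n.a| = %.3f\n",
              x$axis_point_forward[1], x$axis_point_forward[2],
              x$axis_point_forward[3], x$axis_point_inverse[1],
              x$axis_point_inverse[2], x$axis_point_inverse[3],
              x$conditioning))
  invisible(x)
}
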