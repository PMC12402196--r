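# Orthogonal-distance least-squares cylinder fit to a surface patch.
#
# The posterior talar facet is approximately a partial (here ~120 degree)
# cylindrical arc; its fitted axis direction supplies the translation
# direction of the facet-axis motion decomposition. The fit minimises
# sum_i (dist(p_i, axis) - r)^2 over axis direction (2 dof on the sphere),
# axis offset (2 dof in the plane perpendicular to the direction) and radius.

#' Surface patch (bare point set)
#'
#' @param points n x 3 numeric matrix of points (mm), n >= 6 and not
#'   collinear.
#' @return Object of class `surface_patch`.
#' @export
surface_patch <- function(points) {
  points <- as.matrix(points)
  stopifnot(is.numeric(points), ncol(points) == 3)
  if (nrow(points) < 6)
    stop("a cylinder fit needs at least 6 points", call. = FALSE)
  sv <- svd(sweep(points, 2, colMeans(points)))$d
  if (sv[2] <= 1e-9 * max(sv[1], 1))
    stop("points are (near) collinear", call. = FALSE)
  structure(list(points = points), class = "surface_patch")
}

# 2D algebraic (Kasa) circle fit: minimise sum (|q|^2 - 2 c.q - rho)^2.
# Returns list(center, radius, rms of radial residuals) or NULL if singular.
circle_fit_2d <- function(q) {
  A <- cbind(2 * q, 1)
  b <- rowSums(q^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  center <- sol[1:2]
  r2 <- sol[3] + sum(center^2)
  if (r2 <= 0) return(NULL)
  r <- sqrt(r2)
  d <- sqrt(rowSums(sweep(q, 2, center)^2))
  list(center = center, radius = r, rms = sqrt(mean((d - r)^2)))
}

# Quasi-uniform directions on the half sphere (Fibonacci lattice).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # upper half sphere only
  th <- pi * (1 + sqrt(5)) * i
  cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
}

# Given a candidate axis direction, project points into the perpendicular
# plane and circle-fit; returns an initialisation candidate or NULL.
cylinder_init_for_direction <- function(P, d) {
  u <- orthogonal_unit(d); v <- cross3(d, u)
  q <- cbind(P %*% u, P %*% v)
  cf <- circle_fit_2d(q)
  if (is.null(cf)) return(NULL)
  list(direction = d, point = cf$center[1] * u + cf$center[2] * v,
       radius = cf$radius, rms = cf$rms)
}

#' Fit a cylinder to a surface patch
#'
#' Orthogonal-distance nonlinear least squares: the objective is the sum of
#' squared radial residuals `dist(p_i, axis) - r`. Initialisation screens the
#' principal directions of the point cloud together with a quasi-uniform grid
#' of candidate axis directions (each scored by an algebraic circle fit of
#' the projected points), because the smallest-variation principal direction
#' alone can fail on partial-arc patches. The best candidate is refined by
#' Levenberg-Marquardt over a local parameterisation (two direction offsets,
#' two in-plane axis offsets, radius); the refined fit is only accepted if it
#' does not increase the objective.
#'
#' The axis direction sign is canonicalised to a positive dot product with
#' `hint` (a cylinder axis has no intrinsic orientation).
#'
#' @param patch A [surface_patch] (or bare n x 3 point matrix).
#' @param hint 3-vector orienting the reported direction (default global +x).
#' @param grid_n Number of candidate directions screened at initialisation.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return Object of class `cylinder_fit`: `direction` (unit 3-vector),
#'   `point_on_axis` (mm; the axis point closest to the origin), `radius`
#'   (mm), `rms_residual` (mm), `n_points`, `condition_ok`.
#' @examples
#' th <- seq(0, 2 * pi / 3, length.out = 60)
#' pts <- cbind(10 * cos(th), 10 * sin(th), seq(-10, 10, length.out = 60))
#' fit_cylinder(pts)
#' @export
fit_cylinder <- function(patch, hint = c(1, 0, 0), grid_n = 150,
                         max_iter = 200) {
  if (!inherits(patch, "surface_patch")) patch <- surface_patch(patch)
  P <- patch$points
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)
  # coplanarity: scatter condition along the least-variation direction
  if (sv$d[3] <= 1e-7 * sv$d[1])
    stop("ill-conditioned patch: points are (near) coplanar; ",
         "a cylinder fit is not defined", call. = FALSE)

  cands <- list()
  for (k in 1:3) {
    ci <- cylinder_init_for_direction(Pc, sv$v[, k])
    if (!is.null(ci)) cands[[length(cands) + 1]] <- ci
  }
  for (d in asplit(fibonacci_directions(grid_n), 1)) {
    ci <- cylinder_init_for_direction(Pc, as.numeric(d))
    if (!is.null(ci)) cands[[length(cands) + 1]] <- ci
  }
  if (!length(cands))
    stop("cylinder fit failed: no valid initialisation", call. = FALSE)
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "rms"))]]

  # local parameterisation around the initial direction
  d0 <- best$direction
  u0 <- orthogonal_unit(d0); v0 <- cross3(d0, u0)
  c2 <- c(sum(best$point * u0), sum(best$point * v0))
  par0 <- c(0, 0, c2, best$radius)
  resid_fun <- function(par) {
    d <- unitize(d0 + par[1] * u0 + par[2] * v0)
    cpt <- par[3] * u0 + par[4] * v0
    w <- sweep(Pc, 2, cpt)
    w_perp <- w - tcrossprod(w %*% d, d)
    sqrt(rowSums(w_perp^2)) - par[5]
  }
  nlfit <- tryCatch(
    minpack.lm::nls.lm(par0, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, ftol = 1e-10, ptol = 1e-12)),
    error = function(e) NULL)

  direction <- d0; point <- best$point; radius <- best$radius
  rms <- best$rms
  if (!is.null(nlfit)) {
    pr <- nlfit$par
    rms_ref <- sqrt(mean(resid_fun(pr)^2))
    if (is.finite(rms_ref) && rms_ref <= rms && pr[5] > 0) {
      direction <- unitize(d0 + pr[1] * u0 + pr[2] * v0)
      point <- pr[3] * u0 + pr[4] * v0
      radius <- pr[5]
      rms <- rms_ref
    }
  }
  if (radius <= 0)
    stop("cylinder fit failed: non-positive radius", call. = FALSE)
  point <- point + ctr
  point <- point - sum(point * direction) * direction  # closest to origin
  if (sum(direction * hint) < 0) direction <- -direction
  structure(list(direction = direction, point_on_axis = point,
                 radius = radius, rms_residual = rms, n_points = nrow(P),
                 condition_ok = TRUE),
            class = "cylinder_fit")
}

#' Signed radial residuals of a cylinder fit
#'
#' @param patch A [surface_patch] or n x 3 point matrix.
#' @param fit A `cylinder_fit`.
#' @return Numeric vector: `dist(p_i, axis) - radius` (mm) per point.
#' @export
cylinder_residuals <- function(patch, fit) {
  if (!inherits(patch, "surface_patch")) patch <- surface_patch(patch)
  stopifnot(inherits(fit, "cylinder_fit"))
  w <- sweep(patch$points, 2, fit$point_on_axis)
  w_perp <- w - tcrossprod(w %*% fit$direction, fit$direction)
  sqrt(rowSums(w_perp^2)) - fit$radius
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf(
    "<cylinder_fit> axis (%.4f, %.4f, %.4f) through (%.2f, %.2f, %.2f), r = %.3f mm, rms = %.4g mm (%d points)\n",
    x$direction[1], x$direction[2], x$direction[3], x$point_on_axis[1],
    x$point_on_axis[2], x$point_on_axis[3], x$radius, x$rms_residual,
    x$n_points))
  invisible(x)
}
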