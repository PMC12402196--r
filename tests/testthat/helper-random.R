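# Seeded random geometry used across the suite.

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_rotation <- function(min_angle = 0.01, max_angle = pi - 0.01) {
  rodrigues_rotation(random_unit_vector(),
                     stats::runif(1, min_angle, max_angle))
}

random_transform <- function(translation_scale = 20) {
  rigid_transform(random_rotation(),
                  stats::rnorm(3, sd = translation_scale))
}

# max abs difference between two rigid transforms (rotation elements and
# translation entries pooled)
transform_diff <- function(T1, T2) {
  max(abs(T1$rotation - T2$rotation), abs(T1$translation - T2$translation))
}

# exact cylinder samples: radius r, axis z through origin, partial arc
cylinder_arc_points <- function(n, radius = 10, arc_deg = 120, length = 20,
                                sigma = 0) {
  th <- stats::runif(n, -deg2rad_t(arc_deg) / 2, deg2rad_t(arc_deg) / 2)
  z <- stats::runif(n, -length / 2, length / 2)
  pts <- cbind(radius * cos(th), radius * sin(th), z)
  if (sigma > 0) pts <- pts + matrix(stats::rnorm(3 * n, sd = sigma), ncol = 3)
  pts
}

deg2rad_t <- function(x) x * pi / 180
rad2deg_t <- function(x) x * 180 / pi

angle_between_deg <- function(u, v) {
  acos(min(1, abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

cross3_t <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# perpendicular distance of point p from the line (point q, direction d)
line_point_distance <- function(p, q, d) {
  d <- d / sqrt(sum(d^2))
  w <- p - q
  sqrt(sum((w - sum(w * d) * d)^2))
}
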