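test_that("with a = n the facet-axis representation reduces to the helical one", {
  set.seed(31)
  for (i in 1:50) {
    T <- random_transform()
    h <- helical_decompose(T)
    d <- oblique_decompose(T, h$angle_axis$axis)
    expect_equal(d$alpha, h$L, tolerance = 1e-10)
    expect_equal(d$axis_point_forward, h$axis_point, tolerance = 1e-10)
    expect_equal(d$conditioning, 1, tolerance = 1e-12)
    # consistency with composing the helical decomposition
    expect_lt(transform_diff(oblique_compose(d), screw_compose(h)), 1e-10)
  }
})

test_that("perpendicular translation direction raises a singular-configuration error", {
  H <- rodrigues_rotation(c(0, 0, 1), pi / 4)
  T <- rigid_transform(H, c(1, 2, 3))   # nonzero axial component
  expect_error(oblique_decompose(T, c(1, 0, 0)), "singular")
  expect_error(oblique_decompose(identity_transform(), c(1, 0, 0)),
               "zero-rotation")
})

test_that("a constructed oblique motion is recovered exactly", {
  # rotation of 90 deg about the vertical line through (2, 0, 0), plus 3 mm
  # of translation along an oblique direction, composed from its definition
  n <- c(0, 0, 1); phi <- pi / 2
  a <- c(0, sqrt(2) / 2, sqrt(2) / 2)
  x0 <- c(2, 0, 0); alpha0 <- 3
  H <- rodrigues_rotation(n, phi)
  T <- rigid_transform(H, as.numeric((diag(3) - H) %*% x0) + alpha0 * a)
  d <- oblique_decompose(T, a)
  expect_equal(d$angle_axis$angle, phi, tolerance = 1e-10)
  expect_equal(d$angle_axis$axis, n, tolerance = 1e-10)
  expect_equal(d$alpha, alpha0, tolerance = 1e-10)
  expect_equal(d$axis_point_forward, x0, tolerance = 1e-10)

  pair <- axis_pair(T, a)
  expect_gt(pair$separation, 0)
  expect_lt(sqrt(sum(cross3_t(pair$forward$direction,
                              pair$inverse$direction)^2)), 1e-9)
})

test_that("decompose/compose round-trips and links to the helical translation", {
  set.seed(32)
  done <- 0
  while (done < 500) {
    T <- random_transform()
    a <- random_unit_vector()
    h <- helical_decompose(T)
    n <- h$angle_axis$axis
    if (abs(sum(n * a)) <= 0.1) next
    done <- done + 1
    d <- oblique_decompose(T, a)
    # reconstruction via the defining equation
    expect_lt(transform_diff(oblique_compose(d), T), 1e-9)
    # same rotation as the helical decomposition
    expect_equal(d$angle_axis$angle, h$angle_axis$angle, tolerance = 1e-12)
    expect_equal(d$angle_axis$axis, n, tolerance = 1e-10)
    # L = alpha * (n . a); both equal n' t
    expect_equal(h$L, d$alpha * sum(n * d$a), tolerance = 1e-10)
    # |alpha| >= |L|
    expect_gte(abs(d$alpha) + 1e-12, abs(h$L))
    # solvability: the residual translation is perpendicular to n
    expect_lt(abs(sum(n * (T$translation - d$alpha * d$a))), 1e-10)
    # both axis points perpendicular to the axis; axes parallel
    expect_lt(abs(sum(d$axis_point_forward * n)), 1e-9)
    expect_lt(abs(sum(d$axis_point_inverse * n)), 1e-9)
  }
})

test_that("round trip from constructed decompositions recovers the parameters", {
  set.seed(33)
  done <- 0
  while (done < 500) {
    n <- random_unit_vector(); a <- random_unit_vector()
    if (abs(sum(n * a)) <= 0.1) next
    done <- done + 1
    if (sum(n * a) < 0) a <- -a
    phi <- runif(1, 0.05, pi - 0.05)
    alpha <- rnorm(1, sd = 5)
    x <- rnorm(3, sd = 15); x <- x - sum(x * n) * n
    d0 <- list(angle_axis = angle_axis(phi, n), a = a, alpha = alpha,
               axis_point_forward = x)
    T <- oblique_compose(d0)
    d <- oblique_decompose(T, a)
    expect_equal(d$angle_axis$angle, phi, tolerance = 1e-9)
    expect_equal(d$alpha, alpha, tolerance = 1e-9)
    expect_equal(d$axis_point_forward, x, tolerance = 1e-7)
  }
})

test_that("axis separation is zero in the helical case and frame-invariant", {
  set.seed(34)
  T <- random_transform()
  h <- helical_decompose(T)
  expect_lt(axis_pair(T, h$angle_axis$axis)$separation, 1e-9)

  # equivariance: a global change of frame leaves the separation unchanged
  for (i in 1:20) {
    T <- random_transform()
    a <- random_unit_vector()
    n <- helical_decompose(T)$angle_axis$axis
    if (abs(sum(n * a)) <= 0.1) next
    sep <- axis_pair(T, a)$separation
    G <- random_transform()
    T_g <- compose_transform(G, compose_transform(T, invert_transform(G)))
    a_g <- as.numeric(G$rotation %*% a)
    expect_equal(axis_pair(T_g, a_g)$separation, sep, tolerance = 1e-8)
  }
})
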