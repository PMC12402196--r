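test_that("helical decomposition handles null and pure-translation motion", {
  d0 <- helical_decompose(identity_transform())
  expect_true(d0$pure_translation)
  expect_true(d0$angle_axis$degenerate)
  expect_equal(d0$L, 0)

  dt <- helical_decompose(rigid_transform(diag(3), c(3, 4, 0)))
  expect_true(dt$pure_translation)
  expect_equal(dt$L, 5)
  expect_equal(dt$angle_axis$axis, c(0.6, 0.8, 0))
  expect_lt(transform_diff(screw_compose(dt),
                           rigid_transform(diag(3), c(3, 4, 0))), 1e-12)
})

test_that("helical decomposition recovers a known off-origin screw", {
  # quarter turn about the vertical line through (1, 0, 0), no axial slide:
  # oracle built by composing the motion from pose algebra
  H <- rodrigues_rotation(c(0, 0, 1), pi / 2)
  x0 <- c(1, 0, 0)
  T <- rigid_transform(H, as.numeric((diag(3) - H) %*% x0))
  d <- helical_decompose(T)
  expect_equal(d$angle_axis$angle, pi / 2)
  expect_equal(d$angle_axis$axis, c(0, 0, 1))
  expect_equal(d$L, 0, tolerance = 1e-12)
  expect_equal(d$axis_point, c(1, 0, 0))

  # pure screw on a coordinate axis
  d2 <- helical_decompose(rigid_transform(H, c(0, 0, 5)))
  expect_equal(d2$L, 5)
  expect_equal(d2$axis_point, c(0, 0, 0))
})

test_that("decompose/compose round-trips on random transforms", {
  set.seed(21)
  for (i in 1:500) {
    T <- random_transform()
    d <- helical_decompose(T)
    expect_false(d$pure_translation)
    # axis point is the unique one perpendicular to the axis
    expect_lt(abs(sum(d$axis_point * d$angle_axis$axis)), 1e-9)
    expect_lt(transform_diff(screw_compose(d), T), 1e-9)
    # n' (I - H) = 0
    expect_lt(max(abs(crossprod(d$angle_axis$axis, diag(3) - T$rotation))),
              1e-9)
    # points on the axis displace purely along n by L
    disp <- apply_transform(T, d$axis_point) - d$axis_point
    expect_lt(sqrt(sum((disp - d$L * d$angle_axis$axis)^2)), 1e-9)
  }
})

test_that("compose then decompose returns the same screw parameters", {
  set.seed(22)
  for (i in 1:500) {
    n <- random_unit_vector()
    phi <- runif(1, 0.05, pi - 0.05)
    L <- rnorm(1, sd = 5)
    x <- rnorm(3, sd = 15)
    x <- x - sum(x * n) * n   # canonical: perpendicular to the axis
    d0 <- structure(list(angle_axis = angle_axis(phi, n), L = L,
                         axis_point = x, pure_translation = FALSE),
                    class = "screw_decomposition")
    d <- helical_decompose(screw_compose(d0))
    expect_equal(d$angle_axis$angle, phi, tolerance = 1e-9)
    expect_equal(d$angle_axis$axis, n, tolerance = 1e-9)
    expect_equal(d$L, L, tolerance = 1e-9)
    expect_equal(d$axis_point, x, tolerance = 1e-7)
  }
})

test_that("forward and inverse transformations share the helical axis line", {
  set.seed(23)
  for (i in 1:200) {
    T <- random_transform()
    d <- helical_decompose(T)
    di <- helical_decompose(invert_transform(T))
    # same line: directions (anti)parallel ...
    expect_lt(sqrt(sum(cross3_t(d$angle_axis$axis, di$angle_axis$axis)^2)),
              1e-9)
    # ... and each axis point lies on the other's axis
    expect_lt(line_point_distance(di$axis_point, d$axis_point,
                                  d$angle_axis$axis), 1e-9)
    expect_lt(line_point_distance(d$axis_point, di$axis_point,
                                  di$angle_axis$axis), 1e-9)
  }
})
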