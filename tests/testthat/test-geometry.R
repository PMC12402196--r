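test_that("skew matrix realises the cross product and is antisymmetric", {
  expect_equal(skew_matrix(c(0, 0, 0)), matrix(0, 3, 3))
  expect_equal(as.numeric(skew_matrix(c(0, 0, 1)) %*% c(1, 0, 0)),
               c(0, 1, 0))
  set.seed(11)
  for (i in 1:20) {
    v <- rnorm(3); w <- rnorm(3)
    S <- skew_matrix(v)
    expect_equal(S + t(S), matrix(0, 3, 3))
    expect_equal(as.numeric(S %*% w),
                 c(v[2] * w[3] - v[3] * w[2],
                   v[3] * w[1] - v[1] * w[3],
                   v[1] * w[2] - v[2] * w[1]))
  }
})

test_that("Rodrigues rotation has the defining properties", {
  expect_equal(rodrigues_rotation(c(0, 0, 1), 0), diag(3))
  expect_equal(as.numeric(rodrigues_rotation(c(0, 0, 1), pi / 2) %*% c(1, 0, 0)),
               c(0, 1, 0))
  # three-fold symmetry about the diagonal permutes the basis vectors
  H3 <- rodrigues_rotation(rep(1, 3) / sqrt(3), 2 * pi / 3)
  expect_equal(as.numeric(H3 %*% c(1, 0, 0)), c(0, 1, 0))
  expect_equal(as.numeric(H3 %*% c(0, 1, 0)), c(0, 0, 1))
  set.seed(12)
  for (i in 1:50) {
    n <- random_unit_vector(); phi <- runif(1, 0, pi)
    H <- rodrigues_rotation(n, phi)
    expect_lt(max(abs(crossprod(H) - diag(3))), 1e-12)
    expect_equal(det(H), 1, tolerance = 1e-12)
    expect_equal(as.numeric(H %*% n), n, tolerance = 1e-12)   # axis fixed
    expect_equal(sum(diag(H)), 1 + 2 * cos(phi), tolerance = 1e-12)
  }
  expect_error(rodrigues_rotation(c(1, 1, 0), 1), "unit")
})

test_that("relative rotation carries pose A onto pose B", {
  M <- random_rotation()
  expect_equal(relative_rotation(body_pose(M), body_pose(M)), diag(3))
  H30 <- rodrigues_rotation(c(0, 0, 1), pi / 6)
  expect_equal(relative_rotation(body_pose(diag(3)), body_pose(H30)), H30)
  set.seed(13)
  for (i in 1:200) {
    MA <- random_rotation(); MB <- random_rotation()
    H <- relative_rotation(body_pose(MA), body_pose(MB))
    expect_lt(max(abs(H %*% MA - MB)), 1e-10)
  }
  expect_error(relative_rotation(matrix(1, 3, 3), diag(3)), "orthonormal")
})

test_that("angle-axis extraction round-trips through all branches", {
  aa0 <- rotation_to_angle_axis(diag(3))
  expect_true(aa0$degenerate)
  expect_equal(aa0$angle, 0)

  aa <- rotation_to_angle_axis(rodrigues_rotation(c(0, 0, 1), pi / 2))
  expect_equal(aa$angle, pi / 2)
  expect_equal(aa$axis, c(0, 0, 1))

  # half turn: the antisymmetric-elements formula is singular here
  aap <- rotation_to_angle_axis(diag(c(1, -1, -1)))
  expect_equal(aap$angle, pi)
  expect_equal(abs(aap$axis), c(1, 0, 0))

  set.seed(14)
  for (i in 1:500) {
    H <- random_rotation(min_angle = 1e-6, max_angle = pi)
    aa <- rotation_to_angle_axis(H)
    expect_false(aa$degenerate)
    expect_true(aa$angle >= 0 && aa$angle <= pi)
    expect_lt(max(abs(rodrigues_rotation(aa$axis, aa$angle) - H)), 1e-10)
  }
  expect_error(rotation_to_angle_axis(diag(c(1, 1, -1))), "orthonormal")
})

test_that("transform algebra: inverse, application and associativity", {
  expect_equal(transform_diff(invert_transform(identity_transform()),
                              identity_transform()), 0)
  set.seed(15)
  for (i in 1:100) {
    T <- random_transform(); p <- rnorm(3, sd = 30)
    expect_lt(transform_diff(compose_transform(invert_transform(T), T),
                             identity_transform()), 1e-10)
    expect_lt(max(abs(apply_transform(invert_transform(T),
                                      apply_transform(T, p)) - p)), 1e-10)
    expect_equal(apply_transform(T, p),
                 as.numeric(T$rotation %*% p) + T$translation)
  }
  for (i in 1:50) {
    T1 <- random_transform(); T2 <- random_transform(); T3 <- random_transform()
    expect_lt(transform_diff(
      compose_transform(compose_transform(T1, T2), T3),
      compose_transform(T1, compose_transform(T2, T3))), 1e-9)
  }
  # matrix form of apply matches row-wise mapping
  T <- random_transform()
  P <- matrix(rnorm(30), ncol = 3)
  expect_equal(apply_transform(T, P),
               t(apply(P, 1, function(p) apply_transform(T, p))))
})
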