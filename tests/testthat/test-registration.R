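test_that("closed-form correspondence fit recovers known rigid motions", {
  set.seed(51)
  P <- matrix(rnorm(60, sd = 15), ncol = 3)
  expect_lt(transform_diff(rigid_fit_correspondences(P, P),
                           identity_transform()), 1e-12)
  for (i in 1:100) {
    G <- random_transform()
    fit <- rigid_fit_correspondences(P, apply_transform(G, P))
    expect_lt(transform_diff(fit, G), 1e-10)
  }
  expect_error(rigid_fit_correspondences(P[1:2, ], P[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(rigid_fit_correspondences(line, line), "collinear")
})

test_that("the correspondence fit is a local optimum under noise", {
  set.seed(52)
  P <- matrix(rnorm(150, sd = 15), ncol = 3)
  G <- random_transform()
  Q <- apply_transform(G, P) + matrix(rnorm(150, sd = 0.5), ncol = 3)
  fit <- rigid_fit_correspondences(P, Q)
  ss <- function(T) sum((apply_transform(T, P) - Q)^2)
  s0 <- ss(fit)
  for (eps in c(1e-3, 1e-2)) {
    for (k in 1:3) {
      ax <- c(0, 0, 0); ax[k] <- 1
      for (sgn in c(-1, 1)) {
        pert_r <- compose_transform(
          rigid_transform(rodrigues_rotation(ax, sgn * eps)), fit)
        pert_t <- rigid_transform(fit$rotation,
                                  fit$translation + sgn * eps * ax)
        expect_gte(ss(pert_r), s0)
        expect_gte(ss(pert_t), s0)
      }
    }
  }
})

test_that("ICP on identical clouds returns the identity immediately", {
  set.seed(53)
  ph <- generate_phantom(phantom_spec(seed = 3, bone_point_count = 300))
  tal <- ph$neutral$talus
  res <- icp_register(tal, tal, icp_params())
  expect_lt(res$rms, 1e-9)
  expect_lt(transform_diff(res$transform, identity_transform()), 1e-9)
  expect_true(res$converged)
})

test_that("ICP recovers a known small displacement of the same surface", {
  ph <- generate_phantom(phantom_spec(seed = 4, bone_point_count = 400))
  tal <- ph$neutral$talus
  G <- rigid_transform(rodrigues_rotation(c(0.2, 0.5, 1) / sqrt(1.29),
                                          deg2rad_t(5)), c(1.5, -1, 0.5))
  moved <- apply_transform(G, tal$vertices)
  res <- icp_register(moved, tal, icp_params())
  expect_true(res$converged)
  expect_lt(res$rms, 1e-6)
  rec <- compose_transform(res$transform, G)
  aa <- rotation_to_angle_axis(rec$rotation)
  expect_lt(aa$angle, 1e-4)
  expect_lt(sqrt(sum(rec$translation^2)), 1e-3)
  # objective is monotone non-increasing across iterations
  expect_true(all(diff(res$rms_history) <= 1e-12))
})

test_that("dissimilar clouds fail gracefully", {
  set.seed(54)
  A <- matrix(rnorm(300, sd = 5), ncol = 3)
  B <- sweep(matrix(rnorm(300, sd = 1), ncol = 3), 2, c(100, 0, 0), "+")
  res <- icp_register(A, B, icp_params(max_iterations = 20))
  expect_true(is.finite(res$rms))
  expect_true(res$rms > 0.1 || !res$converged)
  expect_error(icp_register(matrix(numeric(0), 0, 3), B), "empty")
})

test_that("calcaneus motion: identity for identical postures, exact on the phantom", {
  ph <- generate_phantom(phantom_spec(seed = 5, bone_point_count = 400))
  params <- icp_params(subsample = 400, seed = 5)
  self <- calcaneus_motion(ph$neutral, ph$neutral, params)
  expect_lt(transform_diff(self, identity_transform()), 1e-9)

  T_inv <- calcaneus_motion(ph$neutral, ph$inverted, params)
  gt <- ph$ground_truth$posture_motions$inverted
  rec <- compose_transform(T_inv, invert_transform(gt))
  expect_lt(rotation_to_angle_axis(rec$rotation)$angle, 1e-4)
  expect_lt(sqrt(sum(rec$translation^2)), 1e-3)
})

test_that("calcaneus motion under surface noise stays within frozen tolerance", {
  # tolerance frozen from the pre-build Monte-Carlo (20 replicates at
  # sigma = 0.05 mm): recovered rotations were within 0.01 deg and
  # translations within 0.01 mm, well inside the contractual 0.2 deg/0.1 mm
  ph <- generate_phantom(phantom_spec(seed = 6, surface_noise_sigma = 0.05))
  params <- icp_params(subsample = 500, seed = 6)
  T_inv <- calcaneus_motion(ph$neutral, ph$inverted, params)
  gt <- ph$ground_truth$posture_motions$inverted
  rec <- compose_transform(T_inv, invert_transform(gt))
  expect_lt(rad2deg_t(rotation_to_angle_axis(rec$rotation)$angle), 0.2)
  expect_lt(sqrt(sum(rec$translation^2)), 0.1)
})

test_that("calcaneus motion is invariant under a joint rigid pre-transform", {
  ph <- generate_phantom(phantom_spec(seed = 7, bone_point_count = 400))
  params <- icp_params(subsample = 400, seed = 7)
  base <- calcaneus_motion(ph$neutral, ph$inverted, params)
  G <- rigid_transform(rodrigues_rotation(c(0, 1, 0), deg2rad_t(12)),
                       c(4, -3, 6))
  moved <- list(
    talus = apply_transform(G, ph$inverted$talus$vertices),
    calcaneus = apply_transform(G, ph$inverted$calcaneus$vertices))
  again <- calcaneus_motion(ph$neutral, moved, params)
  expect_lt(transform_diff(base, again), 1e-6)
})
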