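test_that("canonical landmark placement gives the identity basis", {
  lm <- foot_landmarks(c(0, 0, 0), c(200, 0, 0), c(0, 0, 0), c(0, 0, 1),
                       side = "right")
  fr <- build_foot_frame(lm)
  expect_equal(fr$basis, diag(3), ignore_attr = TRUE)
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(det(fr$basis), 1, tolerance = 1e-12)
})

test_that("frame construction is equivariant under rigid motion of the landmarks", {
  set.seed(61)
  lm0 <- foot_landmarks(c(-60, 5, -50), c(120, -3, -47), c(0, 0, -50),
                        c(0.02, -0.01, 1), side = "right")
  fr0 <- build_foot_frame(lm0)
  for (i in 1:20) {
    G <- random_transform(translation_scale = 50)
    lm <- foot_landmarks(
      apply_transform(G, lm0$calcaneal_tuberosity),
      apply_transform(G, lm0$second_metatarsal_head),
      apply_transform(G, lm0$plantar_point),
      as.numeric(G$rotation %*% lm0$plantar_normal), side = "right")
    fr <- build_foot_frame(lm)
    expect_lt(max(abs(fr$basis - G$rotation %*% fr0$basis)), 1e-10)
  }
})

test_that("degenerate landmarks are rejected", {
  expect_error(foot_landmarks(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)),
               "coincide")
  expect_error(build_foot_frame(
    foot_landmarks(c(0, 0, 0), c(0, 0, 10), c(0, 0, 0), c(0, 0, 1))),
    "parallel")
})

test_that("axis orientation angles match direct constructions", {
  fr <- canonical_foot_frame()
  o45 <- axis_orientation_angles(c(1, 0, 1) / sqrt(2), fr)
  expect_equal(o45$sagittal_inclination, 45)
  expect_equal(o45$horizontal_deviation, 0)

  o20 <- axis_orientation_angles(c(cos(deg2rad_t(20)), sin(deg2rad_t(20)), 0),
                                 fr)
  expect_equal(o20$sagittal_inclination, 0)
  expect_equal(o20$horizontal_deviation, 20)

  # an axis pointing posteriorly is flipped to its anterior representative
  oflip <- axis_orientation_angles(-c(1, 0, 1) / sqrt(2), fr)
  expect_equal(oflip$sagittal_inclination, 45)

  # vertical axis: deviation undefined, flagged
  overt <- axis_orientation_angles(c(0, 0, 1), fr)
  expect_false(overt$deviation_defined)
  expect_true(is.na(overt$horizontal_deviation))
})

test_that("angles -> direction -> angles is the identity; left feet mirror the sign", {
  set.seed(62)
  fr <- canonical_foot_frame()
  for (i in 1:50) {
    inc <- runif(1, -80, 80); dev <- runif(1, -170, 170)
    ax <- direction_from_angles(inc, dev, fr)
    o <- axis_orientation_angles(ax, fr)
    if (abs(dev) > 90) {   # posterior axis flipped to anterior representative
      expect_equal(o$sagittal_inclination, -inc, tolerance = 1e-9)
    } else {
      expect_equal(o$sagittal_inclination, inc, tolerance = 1e-9)
      expect_equal(o$horizontal_deviation, dev, tolerance = 1e-9)
    }
  }
  # the reference subtalar-axis orientation round-trips exactly
  ax <- direction_from_angles(40, 20, fr)
  o <- axis_orientation_angles(ax, fr)
  expect_equal(o$sagittal_inclination, 40, tolerance = 1e-9)
  expect_equal(o$horizontal_deviation, 20, tolerance = 1e-9)

  # same geometric axis, left-side frame: medial deviation keeps its sign
  frl <- structure(list(origin = c(0, 0, 0), basis = diag(3), side = "left"),
                   class = "foot_frame")
  axl <- direction_from_angles(40, 20, frl)
  ol <- axis_orientation_angles(axl, frl)
  expect_equal(ol$horizontal_deviation, 20, tolerance = 1e-9)
  expect_equal(axl[2], -ax[2])   # mirrored construction
})

test_that("landmark files round-trip through the key-value format", {
  lm <- foot_landmarks(c(-60.25, 0.5, -50), c(120, 0.125, -48.5),
                       c(0, 0, -50), c(0, 0, 1), side = "left")
  f <- withr::local_tempfile(fileext = ".txt")
  write_landmarks(lm, f)
  lm2 <- read_landmarks(f)
  expect_equal(lm2, lm)
  expect_error(read_landmarks(withr::local_tempfile(fileext = ".txt")),
               "no such file")
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("calcaneal_tuberosity: 0 0 0", bad)
  expect_error(read_landmarks(bad), "missing landmark keys")
})
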