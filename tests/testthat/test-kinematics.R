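# Back-projection, joint angles and the evaluation metrics.

test_that("depth sampling is a zero-excluding 3x3 median", {
  d <- matrix(1000L, 20, 20)
  expect_equal(sample_depth(d, c(10, 10)), 1000)

  d2 <- matrix(0L, 5, 5)
  d2[2:4, 2:4] <- as.integer(c(0, 0, 0, 0, 998, 1000, 1002, 0, 0))
  expect_equal(sample_depth(d2, c(2, 2)), 1000)

  expect_true(is.na(sample_depth(matrix(0L, 5, 5), c(2, 2))))
  expect_true(is.na(sample_depth(d, c(100, 2))))  # out of image
})

test_that("back-projection follows the pinhole model and inverts projection", {
  cam <- camera_model(800, 820, 320, 240)
  expect_equal(unname(backproject(c(320, 240), 1000, cam)), c(0, 0, 1000))
  expect_equal(unname(backproject(c(320 + 800, 240), 1000, cam)),
               c(1000, 0, 1000))
  expect_error(backproject(c(1, 1), 0, cam), "positive")

  set.seed(21)
  for (rep in 1:25) {
    px <- runif(2, 0, c(640, 480))
    z <- runif(1, 300, 4000)
    expect_equal(unname(project_point(backproject(px, z, cam), cam)),
                 unname(px), tolerance = 1e-9)
  }

  # depth_unit scales raw counts to millimetres
  cam2 <- camera_model(800, 800, 320, 240, depth_unit = 0.5)
  expect_equal(unname(backproject(c(320, 240), 1000, cam2))[3], 500)
})

test_that("limb vectors point from the middle joint outwards", {
  uv <- joint_vectors(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(uv$u, c(1, 0, 0))
  expect_equal(uv$v, c(0, -1, 0))

  expect_equal(joint_vectors(c(1, 2, 3), c(1, 2, 3), c(0, 0, 0))$u, c(0, 0, 0))

  set.seed(2)
  for (rep in 1:10) {
    l <- matrix(rnorm(9), 3)
    uv <- joint_vectors(l[1, ], l[2, ], l[3, ])
    expect_equal(uv$u + l[1, ], l[2, ])
    expect_equal(uv$v + l[3, ], l[2, ])
  }
})

test_that("3D angles match closed-form values and are scale/symmetry invariant", {
  expect_equal(angle_3d(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_3d(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(angle_3d(c(1, 1, 0), c(1, 0, 0)), 45)
  # direct evaluation: u.v = 2 + 2 - 4 = 0 with |u| = |v| = 3
  expect_equal(angle_3d(c(1, 2, 2), c(2, 1, -2)), 90, tolerance = 1e-9)
  expect_equal(angle_3d(c(1, 2, 2), c(2, 2, 1)),
               acos(8 / 9) * 180 / pi, tolerance = 1e-9)
  expect_error(angle_3d(c(0, 0, 0), c(1, 0, 0), joint = "KneeR"), "KneeR")

  set.seed(4)
  for (rep in 1:20) {
    u <- rnorm(3); v <- rnorm(3)
    th <- angle_3d(u, v)
    expect_gte(th, 0); expect_lte(th, 180)
    expect_equal(angle_3d(v, u), th)
    expect_equal(angle_3d(3.7 * u, 0.2 * v), th, tolerance = 1e-9)
  }
})

test_that("sagittal angles equal 3D angles of the projected vectors", {
  expect_equal(angle_sagittal(c(1, 0, 5), c(0, 1, 5), "z"), 90)
  u <- c(1, 2, 0); v <- c(-1, 0.5, 0)
  expect_equal(angle_sagittal(u, v, "z"), angle_3d(u, v))
  expect_error(angle_sagittal(c(0, 0, 1), c(1, 0, 0), "z"), "degenerate")

  set.seed(6)
  for (rep in 1:10) {
    u <- rnorm(3); v <- rnorm(3)
    for (ax in 1:3) {
      up <- u; vp <- v; up[ax] <- 0; vp[ax] <- 0
      expect_equal(angle_sagittal(u, v, c("x", "y", "z")[ax]),
                   angle_3d(up, vp))
    }
  }
})

test_that("AJPE is the mean over markers of per-marker mean errors", {
  grid <- expand.grid(frame_index = 0:9, marker_id = sprintf("m%d", 0:11))
  truth <- tibble::tibble(frame_index = grid$frame_index,
                          marker_id = as.character(grid$marker_id),
                          x_mm = rnorm(120), y_mm = rnorm(120),
                          z_mm = 1000 + rnorm(120))
  expect_equal(joint_position_error(truth, truth)$ajpe_mm, 0)

  pred <- truth
  pred$x_mm[pred$marker_id == "m3"] <- pred$x_mm[pred$marker_id == "m3"] + 3
  r <- joint_position_error(pred, truth)
  expect_equal(r$per_marker$mean_error_mm[r$per_marker$marker_id == "m3"], 3)
  expect_equal(r$ajpe_mm, 0.25)

  # random offsets against a flat-loop oracle
  set.seed(13)
  pred2 <- truth
  pred2$x_mm <- pred2$x_mm + rnorm(120)
  pred2$y_mm <- pred2$y_mm + rnorm(120)
  pred2$z_mm <- pred2$z_mm + rnorm(120)
  r2 <- joint_position_error(pred2, truth)
  per <- numeric(0)
  for (m in unique(truth$marker_id)) {
    errs <- c()
    for (f in 0:9) {
      a <- pred2[pred2$marker_id == m & pred2$frame_index == f, ]
      b <- truth[truth$marker_id == m & truth$frame_index == f, ]
      errs <- c(errs, sqrt((a$x_mm - b$x_mm)^2 + (a$y_mm - b$y_mm)^2 +
                             (a$z_mm - b$z_mm)^2))
    }
    per[m] <- mean(errs)
  }
  expect_equal(r2$ajpe_mm, mean(per), tolerance = 1e-12)

  # missing predictions are excluded and counted
  pred3 <- truth
  pred3$x_mm[1] <- NA
  r3 <- joint_position_error(pred3, truth)
  expect_equal(sum(r3$per_marker$n_missing), 1)
  expect_equal(r3$ajpe_mm, 0)
  expect_error(joint_position_error(truth[0, ], truth), "overlapping")
})

test_that("mean angle error averages per-joint absolute deviations", {
  grid <- expand.grid(frame_index = 0:19,
                      joint_name = c("ShoulderL", "ShoulderR", "ElbowL",
                                     "ElbowR", "HipL", "HipR", "KneeL",
                                     "KneeR"))
  truth <- tibble::tibble(frame_index = grid$frame_index,
                          joint_name = as.character(grid$joint_name),
                          theta_deg = runif(160, 60, 120))
  expect_equal(mean_angle_error(truth, truth)$mean_angle_error_deg, 0)

  pred <- truth
  pred$theta_deg[pred$joint_name == "KneeR"] <-
    pred$theta_deg[pred$joint_name == "KneeR"] + 1
  expect_equal(mean_angle_error(pred, truth)$mean_angle_error_deg, 0.125)

  set.seed(17)
  pred2 <- truth
  pred2$theta_deg <- pred2$theta_deg + rnorm(160)
  r <- mean_angle_error(pred2, truth)
  oracle <- mean(tapply(abs(pred2$theta_deg - truth$theta_deg),
                        truth$joint_name, mean))
  expect_equal(r$mean_angle_error_deg, oracle, tolerance = 1e-12)
})

test_that("angle series flag missing 3D input instead of interpolating", {
  det <- tibble::tibble(
    frame_index = rep(0:1, each = 3),
    marker_id = rep(c("a", "b", "c"), 2),
    x_mm = c(0, 1, 1, 0, 1, 1), y_mm = c(0, 0, 1, 0, 0, NA),
    z_mm = 1000
  )
  joints <- list(list(name = "j", ids = c("a", "b", "c")))
  ang <- compute_angles(det, joints)
  expect_equal(ang$theta_deg[1], 90)
  expect_true(is.na(ang$theta_deg[2]))
})
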