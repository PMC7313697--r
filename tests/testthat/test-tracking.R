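# Kalman filtering, search windows and the per-frame tracking state machine.

# Independent textbook Kalman filter (plain matrix algebra, written
# separately from the package implementation) for the agreement check.
reference_kf <- function(x0, P0, zs, q, r) {
  A <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 0), c(0, 0, 0, 1))
  H <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  Q <- q * diag(4); R <- r * diag(2)
  x <- x0; P <- P0
  out <- list()
  for (i in seq_len(nrow(zs))) {
    x <- A %*% x
    P <- A %*% P %*% t(A) + Q
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    x <- x + K %*% (zs[i, ] - H %*% x)
    P <- (diag(4) - K %*% H) %*% P
    out[[i]] <- list(x = as.vector(x), P = (P + t(P)) / 2)
  }
  out
}

test_that("prediction extrapolates with constant velocity", {
  st <- new_track_state("m", c(10, 10))
  expect_equal(kalman_predict(st)$x[1:2], c(10, 10))
  st$x <- c(10, 10, 2, -1)
  expect_equal(kalman_predict(st)$x[1:2], c(12, 9))
  # covariance grows under prediction
  expect_gt(sum(diag(kalman_predict(st)$P)), sum(diag(st$P)))
  bad <- st; bad$initialized <- FALSE
  expect_error(kalman_predict(bad), "uninitialized")
})

test_that("update corrects towards the measurement and shrinks covariance", {
  st <- new_track_state("m", c(5, 5))
  pred <- kalman_predict(st)
  upd <- kalman_update(pred, pred$x[1:2])
  expect_equal(upd$x[1:2], pred$x[1:2])      # zero innovation
  expect_lt(sum(diag(upd$P)), sum(diag(pred$P)))
  expect_equal(upd$frames_since_detection, 0L)

  # r -> 0 limit: posterior equals the measurement
  st0 <- new_track_state("m", c(5, 5), track_params(measurement_noise = 1e-12))
  upd <- kalman_update(kalman_predict(st0), c(9, 3))
  expect_equal(upd$x[1:2], c(9, 3), tolerance = 1e-6)

  expect_error(kalman_update(pred, c(NA, 1)), "non-finite")
})

test_that("velocity estimate converges on an exact constant-velocity track", {
  st <- new_track_state("m", c(0, 0))
  for (k in 1:20) {
    st <- kalman_predict(st)
    st <- kalman_update(st, c(2 * k, -1.5 * k))
  }
  expect_equal(st$x[3:4], c(2, -1.5), tolerance = 1e-3)
})

test_that("filter agrees with an independent implementation on random sequences", {
  set.seed(99)
  for (rep in 1:5) {
    z <- matrix(cumsum(rnorm(40)), ncol = 2)
    st <- new_track_state("m", c(z[1, 1], z[1, 2]),
                          track_params(process_noise = 0.05,
                                       measurement_noise = 2))
    ref <- reference_kf(st$x, st$P, z, 0.05, 2)
    for (i in seq_len(nrow(z))) {
      st <- kalman_update(kalman_predict(st), z[i, ])
      expect_equal(st$x, ref[[i]]$x, tolerance = 1e-9)
      expect_equal(st$P, ref[[i]]$P, tolerance = 1e-9)
    }
  }
})

test_that("ROI windows are centered, scaled and clipped", {
  mk <- list(ref_diag = 20)
  r <- roi_window(c(200, 150), mk, 3, c(640, 480))
  expect_equal(c(r$x0, r$x1), c(170, 230))
  expect_equal(c(r$y0, r$y1), c(120, 180))

  r <- roi_window(c(0, 0), mk, 3, c(640, 480))
  expect_equal(c(r$x0, r$y0), c(0, 0))
  expect_equal(c(r$x1, r$y1), c(30, 30))

  set.seed(5)
  for (rep in 1:50) {
    px <- runif(2, 0, c(639, 479))
    k <- runif(1, 1, 6)
    r <- roi_window(px, mk, k, c(640, 480))
    expect_true(px[1] >= r$x0 - 0.5 && px[1] <= r$x1 + 0.5)
    expect_true(px[2] >= r$y0 - 0.5 && px[2] <= r$y1 + 0.5)
    expect_true(r$x0 >= 0 && r$y0 >= 0 && r$x1 <= 639 && r$y1 <= 479)
  }
})

test_that("a visible marker is detected in the ROI within a pixel of truth", {
  dir <- withr::local_tempdir()
  scene <- one_marker_scene()
  pos <- lapply(0:9, function(t) list(Probe = c(3 * t, 2 * t)))
  ds <- write_custom_dataset(dir, scene, pos)
  res <- mm_track(dir)
  expect_true(all(res$detections$status == "detected"))
  cmp <- dplyr::inner_join(res$detections, ds$ground_truth,
                           by = c("frame_index", "marker_id"))
  expect_true(all(abs(cmp$u_px.x - cmp$u_px.y) <= 1))
  expect_true(all(abs(cmp$v_px.x - cmp$v_px.y) <= 1))
})

test_that("a marker teleporting outside the ROI is recovered by the whole-image pass", {
  dir <- withr::local_tempdir()
  scene <- one_marker_scene()
  # a 104 px jump: well outside the ROI (half-side ~60 px) yet plausible
  # under the position z-scores, so the fallback can accept it
  pos <- c(lapply(0:4, function(t) list(Probe = c(0, 0))),
           lapply(0:4, function(t) list(Probe = c(130, -60))))
  write_custom_dataset(dir, scene, pos)
  res <- mm_track(dir)
  expect_true(all(res$detections$status == "detected"))
  expect_gt(abs(res$detections$u_px[6] - res$detections$u_px[5]), 100)
})

test_that("occlusion yields estimates bounded by the drift gate", {
  dir <- withr::local_tempdir()
  scene <- one_marker_scene()
  # marker moves steadily; an occluder hides it for frames 6..15
  pos <- lapply(0:19, function(t) list(Probe = c(8 * t - 40, 0)))
  occl <- function(t) {
    if (t >= 6 && t <= 15) list(c(0, 639, 0, 479)) else list()
  }
  ds <- write_custom_dataset(dir, scene, pos, occluders = occl)
  cfg <- ds$config
  cfg$track_params <- track_params(tau_drift = 20)
  res <- mm_track(dir, config = cfg)
  det <- res$detections
  expect_equal(det$status[7:16], rep("estimated", 10))
  expect_equal(det$status[1:6], rep("detected", 6))
  expect_equal(det$status[17:20], rep("detected", 4))
  # drift bound against the last confirmed detection
  last_det <- c(det$u_px[6], det$v_px[6])
  for (i in 7:16) {
    d <- sqrt((det$u_px[i] - last_det[1])^2 + (det$v_px[i] - last_det[2])^2)
    expect_lte(d, 20 + 1e-9)
  }
})

test_that("tracks become lost after max_lost_frames and reacquire on detection", {
  dir <- withr::local_tempdir()
  scene <- one_marker_scene()
  pos <- lapply(0:14, function(t) list(Probe = c(0, 0)))
  occl <- function(t) if (t >= 2 && t <= 9) list(c(0, 639, 0, 479)) else list()
  ds <- write_custom_dataset(dir, scene, pos, occluders = occl)
  cfg <- ds$config
  cfg$track_params <- track_params(max_lost_frames = 3)
  res <- mm_track(dir, config = cfg)
  st <- res$detections$status
  expect_equal(st[3:5], rep("estimated", 3))   # within max_lost_frames
  expect_equal(st[6:10], rep("lost", 5))
  expect_equal(st[11:15], rep("detected", 5))  # reacquired
})
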