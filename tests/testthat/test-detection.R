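# HSV gating, contour candidates, and the feature-similarity chain.

solid_image <- function(rgb, h = 8, w = 8) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

test_that("HSV gating matches per-pixel range checks, including hue wrap", {
  rng <- markermotion:::marker_hsv_range("magenta")
  expect_true(all(mask_by_hsv(solid_image(c(1, 0, 1)), rng$low, rng$high)))
  expect_false(any(mask_by_hsv(solid_image(c(0, 0, 0)), rng$low, rng$high)))

  # image half red (hue wraps near 0/180), half green
  img <- array(0, dim = c(4, 8, 3))
  img[, 1:4, 1] <- 1                       # red, hue 0
  img[, 1:4, 3] <- 0.06                    # push hue slightly below 180
  img[, 5:8, 2] <- 1                       # green
  red_rng <- markermotion:::marker_hsv_range("red")
  expect_gt(red_rng$low[1], red_rng$high[1])  # wrapped range
  m <- mask_by_hsv(img, red_rng$low, red_rng$high)
  # brute-force pixelwise oracle
  for (r in 1:4) for (cc in 1:8) {
    hsv <- grDevices::rgb2hsv(img[r, cc, 1], img[r, cc, 2], img[r, cc, 3],
                              maxColorValue = 1)
    h180 <- hsv[1] * 180; s <- hsv[2] * 255; v <- hsv[3] * 255
    inside <- (h180 >= red_rng$low[1] | h180 <= red_rng$high[1]) &
      s >= red_rng$low[2] & s <= red_rng$high[2] &
      v >= red_rng$low[3] & v <= red_rng$high[3]
    expect_identical(m[r, cc], unname(inside))
  }
  expect_true(all(m[, 1:4]) && !any(m[, 5:8]))

  expect_error(mask_by_hsv(img, c(0, 0), c(10, 255, 255)), "triple")
  expect_error(mask_by_hsv(img, c(0, 200, 0), c(10, 100, 255)), "low <= high")
})

test_that("candidate extraction applies the double area threshold", {
  mask <- matrix(FALSE, 60, 60)
  mask[21:40, 21:40] <- TRUE               # 20x20 square, area 400
  cands <- extract_candidates(mask, ref_area = 400)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$area_A, 400)
  expect_equal(cands[[1]]$convexity, 1)
  expect_equal(cands[[1]]$center, c(29.5, 29.5))  # 0-based bbox center

  # a 3x3 speck is removed by the low gate
  mask2 <- mask
  mask2[3:5, 3:5] <- TRUE
  cands <- extract_candidates(mask2, ref_area = 400)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$area_A, 400)

  # blobs of areas 100/300/500/900 against ref 400: gate keeps [200, 800]
  mask3 <- matrix(FALSE, 40, 140)
  mask3[1:10, 1:10] <- TRUE                # 100
  mask3[1:15, 21:40] <- TRUE               # 300
  mask3[1:20, 51:75] <- TRUE               # 500
  mask3[1:30, 91:120] <- TRUE              # 900
  areas <- vapply(extract_candidates(mask3, ref_area = 400),
                  `[[`, numeric(1), "area_A")
  # oracle: direct pixel-count per blob
  expect_setequal(areas, c(300, 500))
})

test_that("convexity is the contour/hull area ratio", {
  square <- cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))
  expect_equal(convexity(square), 1)
  triangle <- cbind(c(0, 4, 2), c(0, 0, 3))
  expect_equal(convexity(triangle), 1)
  # plus-sign of five unit squares: area 5, hull area 7 (shoelace oracle)
  plus <- cbind(
    c(1, 2, 2, 3, 3, 2, 2, 1, 1, 0, 0, 1),
    c(0, 0, 1, 1, 2, 2, 3, 3, 2, 2, 1, 1)
  )
  shoelace <- function(p) {
    n <- nrow(p); i2 <- c(2:n, 1)
    abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
  }
  hull <- plus[grDevices::chull(plus), ]
  expect_equal(shoelace(plus) / shoelace(hull), 5 / 7)
  expect_equal(convexity(plus), 5 / 7)
  expect_error(convexity(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
})

test_that("running feature statistics equal batch recomputation", {
  st <- new_feature_stats(c(area = 10, convex = 1, x = 0, y = 0))
  st <- update_stats(st, c(area = 10, convex = 1, x = 0, y = 0))
  expect_equal(st$mean[["area"]], 10)
  expect_equal(markermotion:::stats_sd(st)[["area"]], 0)

  st <- new_feature_stats()
  for (v in 1:3) st <- update_stats(st, c(area = v, convex = v, x = v, y = v))
  expect_equal(st$mean[["area"]], 2)
  expect_equal(markermotion:::stats_sd(st)[["x"]], 1)

  set.seed(11)
  vals <- matrix(rnorm(4000, sd = 37), ncol = 4,
                 dimnames = list(NULL, c("area", "convex", "x", "y")))
  st <- new_feature_stats()
  for (i in seq_len(nrow(vals))) st <- update_stats(st, vals[i, ])
  expect_equal(unname(st$mean), unname(colMeans(vals)), tolerance = 1e-9)
  expect_equal(unname(markermotion:::stats_sd(st)),
               unname(apply(vals, 2, sd)), tolerance = 1e-9)
})

test_that("z-scores are absolute, floored and capped as documented", {
  st <- new_feature_stats()
  st <- update_stats(st, c(area = 8, convex = 0.9, x = 1, y = 1))
  st <- update_stats(st, c(area = 12, convex = 0.9, x = 1, y = 1))
  # mu = 10, sigma = sqrt(8)
  expect_equal(zscore(10, st, "area"), 0)
  expect_equal(zscore(16, st, "area"), 6 / sqrt(8))
  # sigma = 0 contract: 0 at the mean, cap away from it
  expect_equal(zscore(0.9, st, "convex"), 0)
  expect_equal(zscore(0.7, st, "convex"), 1e6)
  # floor takes over when sigma is degenerate
  expect_equal(zscore(0.7, st, "convex", sigma_floor = 0.05), 0.2 / 0.05)
  # n < 2: no usable statistics yet
  expect_equal(zscore(99, new_feature_stats(c(area = 1, convex = 1,
                                              x = 1, y = 1)), "area"), 0)
})

test_that("similarity conversions follow the printed formulas", {
  expect_equal(pooled_distance(0, 0, 0, 0), 0)
  expect_equal(pooled_distance(1, 1, 1, 1), 1)
  expect_equal(pooled_distance(2, 1, 0, 3), 0.4 * 2 + 0.3 * 1 + 0.15 * 3)

  expect_equal(z_similarity(0), 1)
  expect_equal(z_similarity(1.5), 0.5)
  expect_equal(z_similarity(4), 0)
  expect_equal(z_similarity(3), 0)          # boundary belongs to "otherwise"

  expect_equal(shape_similarity(0), 1)
  expect_equal(shape_similarity(log(2)), 0.5)
  expect_equal(shape_similarity(1), exp(-1))

  expect_equal(overall_similarity(1, 1), 1)
  expect_equal(overall_similarity(0, 0), 0)
  expect_equal(overall_similarity(0.8, 0.4), 0.7)

  # monotonicity over a grid
  d <- seq(0, 5, by = 0.1)
  expect_true(all(diff(z_similarity(d)) <= 0))
  expect_true(all(diff(shape_similarity(d)) < 0))
  expect_true(all(z_similarity(d) >= 0 & z_similarity(d) <= 1))
})

test_that("select_best reproduces an independent evaluation of the equation chain", {
  # a frame with a clean circle and a distorted half-moon blob, same color
  img <- array(0, dim = c(80, 160, 3))
  circ <- shape_template("circle", 22)
  for (px in seq(-12, 12)) for (py in seq(-12, 12)) {
    if (markermotion:::points_in_polygon(px, py, circ)) {
      img[40 + py + 1, 40 + px + 1, ] <- c(1, 0, 1)
    }
    # distorted: same circle with the left half squashed
    q <- c(px * ifelse(px < 0, 0.45, 1), py)
    if (markermotion:::points_in_polygon(q[1], q[2], circ)) {
      img[40 + py + 1, 120 + px + 1, ] <- c(1, 0, 1)
    }
  }
  marker <- marker_spec("t0", "Probe", "magenta", "circle", init_px = c(40, 40))
  params <- detection_params()
  reg <- register_marker(img, marker, params)
  st <- reg$stats
  for (k in 1:3) {       # accumulate a short history so z-scores engage
    st <- update_stats(st, c(area = reg$marker$reference_area + k - 2,
                             convex = 0.95, x = 40 + 0.1 * k, y = 40))
  }
  mask <- mask_by_hsv(img, marker$hsv_low, marker$hsv_high)
  cands <- extract_candidates(mask, params, reg$marker$reference_area)
  expect_length(cands, 2)
  best <- select_best(cands, reg$marker, st, params, last_px = c(40, 40))
  expect_false(is.null(best))

  # independent step-by-step oracle over the whole chain
  mu <- st$mean
  sdv <- sqrt(st$m2 / (st$n - 1))
  fl <- params$sigma_floors
  oracle_sim <- vapply(cands, function(cn) {
    sig <- pmax(sdv, c(fl[["area_frac"]] * mu[["area"]], fl[["convex"]],
                       rep(fl[["center_frac"]] * reg$marker$ref_diag, 2)))
    z <- abs(c(cn$area_A, cn$convexity, cn$center) -
               c(mu[["area"]], mu[["convex"]], mu[["x"]], mu[["y"]])) / sig
    dz <- sum(c(0.4, 0.3, 0.15, 0.15) * z)
    simz <- if (dz < 3) 1 - dz / 3 else 0
    sims <- exp(-shape_distance(cn$contour, reg$marker$reference_contour))
    0.75 * simz + 0.25 * sims
  }, numeric(1))
  expect_equal(best$index, which.max(oracle_sim))
  expect_equal(best$breakdown$sim, max(oracle_sim), tolerance = 1e-12)
  # the matching circle wins over the distorted blob
  expect_lt(abs(best$candidate$center[1] - 40), 1.5)

  # stored breakdown satisfies the conversion equations exactly
  b <- best$breakdown
  expect_equal(b$d_z, 0.4 * b$z_area + 0.3 * b$z_convex +
                 0.15 * b$z_x + 0.15 * b$z_y)
  expect_equal(b$sim_z, if (b$d_z < 3) 1 - b$d_z / 3 else 0)
  expect_equal(b$sim_s, exp(-b$d_s))
  expect_equal(b$sim, 0.75 * b$sim_z + 0.25 * b$sim_s)

  # threshold contract: nothing survives an impossible threshold
  params_hi <- detection_params(tau_sim = 1)
  expect_null(select_best(cands[2], reg$marker, st, params_hi,
                          last_px = c(40, 40)))
})
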