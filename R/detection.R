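# Marker detection: contour candidates, the z-score similarity model and
# non-maximum suppression.
#
# Each candidate blob is described by four features -- contour area A,
# convexity A/C, and the x and y coordinates of its bounding-box center.
# Feature values are compared to the running history of the marker via
# z-scores, pooled into a weighted distance d_z, converted to a similarity,
# and blended with a Hu-moment shape similarity; the top-scoring candidate
# above a threshold wins.

#' Detection parameters
#'
#' Weights and thresholds of the similarity model. The four feature weights
#' (area, convexity, x, y) and the two combination weights (z-similarity,
#' shape similarity) must each sum to 1; the z cutoff of 3 reflects that a
#' candidate more than three standard deviations from the marker's feature
#' history is most likely not the marker.
#'
#' @param weights Named feature weights, default
#'   `c(area = 0.4, convex = 0.3, x = 0.15, y = 0.15)`.
#' @param combo_weights Weights of (z-similarity, shape similarity), default
#'   `c(0.75, 0.25)`.
#' @param z_cutoff Pooled-distance cutoff above which z-similarity is 0
#'   (default 3).
#' @param tau_sim Overall similarity threshold below which candidates are
#'   discarded (default 0.5).
#' @param area_gate Multiplicative gate on candidate area relative to the
#'   registered reference area, default `c(low = 0.5, high = 2)`.
#' @param init_window Side (pixels) of the square window searched around
#'   `init_px` when registering a marker from the first frame (default 121).
#' @param sigma_floors Lower bounds on the per-feature standard deviation
#'   used in z-scoring, as fractions of natural feature scales:
#'   `area_frac` of the running mean area, `convex` absolute, and
#'   `center_frac` of the marker's reference bounding-box diagonal for the
#'   x/y features. A sample standard deviation from a short or constant
#'   history underestimates the inherent pixel-quantization noise; flooring
#'   it keeps z-scores finite and meaningful without weakening outlier
#'   rejection (defaults `c(area_frac = 0.10, convex = 0.05,
#'   center_frac = 0.5)`).
#' @return A list of class `mm_detection_params`.
#' @export
detection_params <- function(weights = c(area = 0.4, convex = 0.3,
                                         x = 0.15, y = 0.15),
                             combo_weights = c(0.75, 0.25),
                             z_cutoff = 3,
                             tau_sim = 0.5,
                             area_gate = c(low = 0.5, high = 2),
                             init_window = 121,
                             sigma_floors = c(area_frac = 0.10,
                                              convex = 0.05,
                                              center_frac = 0.5)) {
  stopifnot(
    abs(sum(weights) - 1) < 1e-9,
    abs(sum(combo_weights) - 1) < 1e-9,
    z_cutoff > 0, tau_sim >= 0, tau_sim <= 1,
    area_gate[[1]] > 0, area_gate[[2]] >= area_gate[[1]]
  )
  structure(
    list(weights = weights, combo_weights = combo_weights,
         z_cutoff = z_cutoff, tau_sim = tau_sim,
         area_gate = c(low = area_gate[[1]], high = area_gate[[2]]),
         init_window = init_window, sigma_floors = sigma_floors),
    class = "mm_detection_params"
  )
}

#' Extract contour candidates from a binary mask
#'
#' Labels connected components of the mask, keeps the external boundary
#' contour of each, and applies the double area threshold: candidates whose
#' pixel area falls outside `[low, high] * ref_area` are removed. Each
#' surviving candidate carries its area `A` (pixel count), convex hull area
#' `C` (hull of the pixel corner points), convexity `A/C`, bounding-box
#' center, and boundary contour.
#'
#' @param mask Logical matrix.
#' @param params [detection_params()].
#' @param ref_area Registered reference area in pixels^2; `NULL` disables
#'   the area gate (used at registration).
#' @return List of candidate lists with elements `contour`, `area_A`,
#'   `hull_area_C`, `convexity`, `center`, `bbox`.
#' @export
extract_candidates <- function(mask, params = detection_params(),
                               ref_area = NULL) {
  stopifnot(is.matrix(mask) || is.array(mask))
  storage.mode(mask) <- "integer"
  if (!any(mask > 0)) return(list())
  lab <- EBImage::bwlabel(t(mask))        # EBImage uses [x, y]
  nobj <- max(lab)
  if (nobj == 0) return(list())
  contours <- EBImage::ocontour(lab)      # 0-based (x, y) boundary pixels
  out <- vector("list", nobj)
  keep <- logical(nobj)
  for (k in seq_len(nobj)) {
    idx <- which(lab == k, arr.ind = TRUE)
    x <- idx[, 1] - 1; y <- idx[, 2] - 1  # 0-based pixel coords
    area <- nrow(idx)
    if (!is.null(ref_area)) {
      lo <- params$area_gate[["low"]] * ref_area
      hi <- params$area_gate[["high"]] * ref_area
      if (area < lo || area > hi) next
    }
    if (area < 3) next                    # too small for any shape features
    # hull over pixel corner points so hull_area >= pixel area
    corners <- cbind(
      c(x - 0.5, x + 0.5, x + 0.5, x - 0.5),
      c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
    )
    hull <- hull_polygon(corners)
    hull_area <- abs(shoelace_area(hull))
    ctr <- c((min(x) + max(x)) / 2, (min(y) + max(y)) / 2)
    out[[k]] <- list(
      contour = contours[[k]],
      area_A = area,
      hull_area_C = hull_area,
      convexity = min(area / hull_area, 1),
      center = ctr,
      bbox = c(xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y))
    )
    keep[k] <- TRUE
  }
  out[keep]
}

#' Running feature statistics of a marker
#'
#' Per-feature running mean and standard deviation (sample, `n - 1`
#' denominator) over the accepted detection history, maintained with
#' Welford's algorithm so they equal a batch recomputation exactly.
#'
#' @param features Optional named numeric vector `(area, convex, x, y)` of a
#'   first accepted detection to seed the statistics (`n = 1`).
#' @return A list of class `mm_feature_stats` with fields `n`, `mean`, `m2`.
#' @export
new_feature_stats <- function(features = NULL) {
  nm <- c("area", "convex", "x", "y")
  st <- structure(
    list(n = 0L,
         mean = setNames(numeric(4), nm),
         m2 = setNames(numeric(4), nm)),
    class = "mm_feature_stats"
  )
  if (!is.null(features)) st <- update_stats(st, features)
  st
}

#' Update running feature statistics with one accepted detection
#'
#' @param stats [new_feature_stats()] object.
#' @param features Named numeric vector with `area`, `convex`, `x`, `y`.
#' @return Updated statistics.
#' @export
update_stats <- function(stats, features) {
  nm <- names(stats$mean)
  x <- unlist(features)[nm]
  if (anyNA(x)) abort("update_stats(): features must include area, convex, x, y")
  n1 <- stats$n + 1L
  delta <- x - stats$mean
  mean_new <- stats$mean + delta / n1
  stats$m2 <- stats$m2 + delta * (x - mean_new)
  stats$mean <- mean_new
  stats$n <- n1
  stats
}

# Per-feature sample standard deviation; NA until n >= 2.
stats_sd <- function(stats) {
  if (stats$n < 2) return(setNames(rep(NA_real_, 4), names(stats$mean)))
  sqrt(pmax(stats$m2, 0) / (stats$n - 1))
}

#' Absolute z-score of a feature value
#'
#' `z = |x - mu| / sigma` against the marker's running statistics. With
#' fewer than two accepted frames, or a degenerate sigma with `x` at the
#' mean, the z-score is 0 (selection then rests on shape similarity); a
#' degenerate sigma with `x` away from the mean returns a large cap that
#' forces the z-similarity to 0.
#'
#' @param x Feature value.
#' @param stats [new_feature_stats()] object.
#' @param feature One of `"area"`, `"convex"`, `"x"`, `"y"`.
#' @param sigma_floor Optional lower bound on sigma (see the
#'   `sigma_floors` argument of [detection_params()]); 0 preserves the
#'   bare contract above.
#' @return Non-negative z-score.
#' @export
zscore <- function(x, stats, feature, sigma_floor = 0) {
  if (stats$n < 2) return(0)
  mu <- stats$mean[[feature]]
  sigma <- max(stats_sd(stats)[[feature]], sigma_floor)
  dev <- abs(x - mu)
  if (sigma < 1e-12) {
    if (dev <= 1e-6) return(0)
    return(1e6)
  }
  dev / sigma
}

#' Pooled z-score distance
#'
#' Weighted sum of the four feature z-scores:
#' `d_z = 0.4 z_area + 0.3 z_convex + 0.15 z_x + 0.15 z_y`.
#'
#' @param z_area,z_convex,z_x,z_y Non-negative z-scores.
#' @param weights Feature weights (see [detection_params()]).
#' @return Pooled distance `d_z >= 0`.
#' @export
pooled_distance <- function(z_area, z_convex, z_x, z_y,
                            weights = c(area = 0.4, convex = 0.3,
                                        x = 0.15, y = 0.15)) {
  weights[["area"]] * z_area + weights[["convex"]] * z_convex +
    weights[["x"]] * z_x + weights[["y"]] * z_y
}

#' Convert a pooled z-distance to a similarity
#'
#' `sim_z = 1 - d_z / 3` when `d_z < 3`, else 0: a candidate more than three
#' pooled standard deviations away is considered not the marker.
#'
#' @param d_z Pooled distance.
#' @param z_cutoff Cutoff (default 3).
#' @return Similarity in `[0, 1]`.
#' @export
z_similarity <- function(d_z, z_cutoff = 3) {
  stopifnot(all(d_z >= 0))
  ifelse(d_z < z_cutoff, 1 - d_z / z_cutoff, 0)
}

#' Overall candidate similarity
#'
#' Weighted blend of the z-score similarity and the shape similarity:
#' `sim = 0.75 sim_z + 0.25 sim_s`.
#'
#' @param sim_z,sim_s Similarities in `[0, 1]`.
#' @param combo_weights Blend weights (default `c(0.75, 0.25)`).
#' @return Similarity in `[0, 1]`.
#' @export
overall_similarity <- function(sim_z, sim_s, combo_weights = c(0.75, 0.25)) {
  combo_weights[1] * sim_z + combo_weights[2] * sim_s
}

# Score one candidate against a marker's reference contour and running
# stats; returns the full breakdown of intermediate values.
score_candidate <- function(candidate, marker, stats, params) {
  ref_contour <- marker$reference_contour
  fl <- params$sigma_floors %||%
    c(area_frac = 0, convex = 0, center_frac = 0)
  floor_area <- fl[["area_frac"]] * stats$mean[["area"]]
  floor_px <- fl[["center_frac"]] * (marker$ref_diag %||% 0)
  zs <- c(
    area = zscore(candidate$area_A, stats, "area", floor_area),
    convex = zscore(candidate$convexity, stats, "convex", fl[["convex"]]),
    x = zscore(candidate$center[1], stats, "x", floor_px),
    y = zscore(candidate$center[2], stats, "y", floor_px)
  )
  d_z <- pooled_distance(zs[["area"]], zs[["convex"]], zs[["x"]], zs[["y"]],
                         params$weights)
  sim_z <- z_similarity(d_z, params$z_cutoff)
  d_s <- shape_distance(candidate$contour, ref_contour)
  sim_s <- shape_similarity(d_s)
  sim <- overall_similarity(sim_z, sim_s, params$combo_weights)
  list(
    z_area = zs[["area"]], z_convex = zs[["convex"]],
    z_x = zs[["x"]], z_y = zs[["y"]],
    d_raw = c(area = abs(candidate$area_A - stats$mean[["area"]]),
              convex = abs(candidate$convexity - stats$mean[["convex"]]),
              x = abs(candidate$center[1] - stats$mean[["x"]]),
              y = abs(candidate$center[2] - stats$mean[["y"]])),
    d_z = d_z, sim_z = sim_z, d_s = d_s, sim_s = sim_s, sim = sim
  )
}

#' Select the best candidate for a marker (non-maximum suppression)
#'
#' Scores every candidate with the full similarity chain, discards those
#' below the similarity threshold, and greedily keeps the highest-scoring
#' survivor. Ties are broken by smaller displacement from the marker's last
#' known position, then by lower candidate index.
#'
#' @param candidates List from [extract_candidates()].
#' @param marker Marker spec (needs `reference_contour`).
#' @param stats [new_feature_stats()] history for this marker.
#' @param params [detection_params()].
#' @param last_px Last known pixel position used for tie-breaks (defaults to
#'   the marker's `init_px`).
#' @return `NULL` if no candidate survives, else a list with `candidate`,
#'   `breakdown` and `index`.
#' @export
select_best <- function(candidates, marker, stats, params = detection_params(),
                        last_px = marker$init_px) {
  if (length(candidates) == 0) return(NULL)
  scored <- lapply(candidates, score_candidate, marker = marker,
                   stats = stats, params = params)
  sims <- vapply(scored, `[[`, numeric(1), "sim")
  ok <- which(sims >= params$tau_sim)
  if (length(ok) == 0) return(NULL)
  disp <- vapply(candidates, function(cnd) {
    sqrt(sum((cnd$center - last_px)^2))
  }, numeric(1))
  best <- ok[order(-sims[ok], disp[ok], ok)][1]
  list(candidate = candidates[[best]], breakdown = scored[[best]],
       index = best)
}

#' Register a marker from its first frame
#'
#' Mirrors the click-based initialization of a recording session: a window
#' around the configured initial pixel position is gated by the marker's HSV
#' range, and the connected component nearest to `init_px` becomes the
#' marker's reference -- its boundary contour, pixel area and bounding-box
#' diagonal are stored on the spec, and the feature statistics are seeded
#' with this first accepted detection.
#'
#' @param image Color frame.
#' @param marker Marker spec with `hsv_low`, `hsv_high`, `init_px`.
#' @param params [detection_params()].
#' @return List with the updated `marker` (reference fields filled), seeded
#'   `stats`, and the registration `center`.
#' @export
register_marker <- function(image, marker, params = detection_params()) {
  half <- floor(params$init_window / 2)
  d <- dim(image)
  x0 <- max(0, round(marker$init_px[1]) - half)
  x1 <- min(d[2] - 1, round(marker$init_px[1]) + half)
  y0 <- max(0, round(marker$init_px[2]) - half)
  y1 <- min(d[1] - 1, round(marker$init_px[2]) + half)
  sub <- image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), , drop = FALSE]
  mask <- mask_by_hsv(sub, marker$hsv_low, marker$hsv_high)
  cands <- extract_candidates(mask, params, ref_area = NULL)
  if (length(cands) == 0) {
    abort(paste0("register_marker(): no blob of color '", marker$color_name,
                 "' near init_px for marker '", marker$id, "'"))
  }
  cands <- lapply(cands, shift_candidate, dx = x0, dy = y0)
  disp <- vapply(cands, function(cnd) {
    sqrt(sum((cnd$center - marker$init_px)^2))
  }, numeric(1))
  best <- cands[[which.min(disp)]]
  marker$reference_contour <- best$contour
  marker$reference_area <- best$area_A
  marker$ref_diag <- sqrt((best$bbox[["xmax"]] - best$bbox[["xmin"]] + 1)^2 +
                          (best$bbox[["ymax"]] - best$bbox[["ymin"]] + 1)^2)
  stats <- new_feature_stats(c(area = best$area_A, convex = best$convexity,
                               x = best$center[1], y = best$center[2]))
  list(marker = marker, stats = stats, center = best$center)
}

# Translate a candidate extracted from a cropped window back to full-frame
# pixel coordinates.
shift_candidate <- function(candidate, dx, dy) {
  candidate$contour[, 1] <- candidate$contour[, 1] + dx
  candidate$contour[, 2] <- candidate$contour[, 2] + dy
  candidate$center <- candidate$center + c(dx, dy)
  candidate$bbox[c("xmin", "xmax")] <- candidate$bbox[c("xmin", "xmax")] + dx
  candidate$bbox[c("ymin", "ymax")] <- candidate$bbox[c("ymin", "ymax")] + dy
  candidate
}
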