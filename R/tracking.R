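# Per-frame tracking state machine: ROI search, whole-frame fallback,
# Kalman occlusion estimation and the drift gate.

# Detect a marker within a pixel rectangle (0-based inclusive bounds).
detect_in_rect <- function(image, rect, marker, stats, dparams, last_px) {
  sub <- image[(rect$y0 + 1):(rect$y1 + 1),
               (rect$x0 + 1):(rect$x1 + 1), , drop = FALSE]
  mask <- mask_by_hsv(sub, marker$hsv_low, marker$hsv_high)
  cands <- extract_candidates(mask, dparams, ref_area = marker$reference_area)
  cands <- lapply(cands, shift_candidate, dx = rect$x0, dy = rect$y0)
  select_best(cands, marker, stats, dparams, last_px = last_px)
}

# Detect a marker on the whole frame, reusing a cached HSV conversion when
# the caller provides one (the expensive shared step of a fallback pass).
detect_full_frame <- function(image, marker, stats, dparams, last_px,
                              hsv_full = NULL) {
  mask <- mask_by_hsv(hsv_full %||% image, marker$hsv_low, marker$hsv_high)
  cands <- extract_candidates(mask, dparams, ref_area = marker$reference_area)
  select_best(cands, marker, stats, dparams, last_px = last_px)
}

#' Track one marker through one frame
#'
#' Runs the per-frame state machine: (1) detection inside the region of
#' interest around the previous position; (2) on failure, detection on the
#' whole frame; (3) on failure, the Kalman prediction is used with status
#' `"estimated"`, subject to the drift gate -- if the predicted position
#' lies farther than `tau_drift` pixels from the last confirmed detection it
#' is clamped to the gate boundary along the prediction direction, so no
#' further drift accumulates. A successful detection triggers the Kalman
#' correction and a feature-statistics update. After `max_lost_frames`
#' consecutive failures the status becomes `"lost"`; a lost marker keeps
#' being searched on the whole frame each frame and the filter is
#' re-initialized (zero velocity) at the first detection that clears the
#' similarity threshold.
#'
#' @param pair Frame pair (list with at least `frame_index` and `color`).
#' @param marker Registered marker spec.
#' @param state [new_track_state()] object.
#' @param stats [new_feature_stats()] history.
#' @param dparams [detection_params()].
#' @param tparams [track_params()].
#' @param hsv_full Optional cached HSV conversion of the full frame.
#' @return List with `record` (one detection row as a tibble), `state` and
#'   `stats`.
#' @export
track_frame <- function(pair, marker, state, stats,
                        dparams = detection_params(),
                        tparams = track_params(),
                        hsv_full = NULL) {
  img <- pair$color
  d <- dim(img)
  image_size <- c(d[2], d[1])
  prev_px <- state$x[1:2]
  was_lost <- identical(state$status, "lost")
  state <- kalman_predict(state)

  hit <- NULL
  if (!was_lost) {
    rect <- roi_window(prev_px, marker, tparams$roi_scale, image_size)
    hit <- detect_in_rect(img, rect, marker, stats, dparams, prev_px)
  }
  if (is.null(hit)) {
    hit <- detect_full_frame(img, marker, stats, dparams, prev_px, hsv_full)
  }

  if (!is.null(hit)) {
    meas <- hit$candidate$center
    if (was_lost) {
      state <- new_track_state(marker$id, meas, tparams)
    } else {
      state <- kalman_update(state, meas)
    }
    stats <- update_stats(stats, c(area = hit$candidate$area_A,
                                   convex = hit$candidate$convexity,
                                   x = meas[1], y = meas[2]))
    rec_px <- meas
    sim <- hit$breakdown$sim
    status <- "detected"
  } else {
    state$frames_since_detection <- state$frames_since_detection + 1L
    status <- if (state$frames_since_detection > tparams$max_lost_frames) {
      "lost"
    } else {
      "estimated"
    }
    # drift gate: clamp the state position to within tau_drift of the last
    # confirmed detection
    disp <- state$x[1:2] - state$last_detected_px
    dist <- sqrt(sum(disp^2))
    if (dist > tparams$tau_drift) {
      state$x[1:2] <- state$last_detected_px +
        disp / dist * tparams$tau_drift
    }
    state$status <- status
    rec_px <- state$x[1:2]
    sim <- NA_real_
  }

  record <- tibble(
    frame_index = pair$frame_index,
    marker_id = marker$id,
    u_px = rec_px[1],
    v_px = rec_px[2],
    similarity = sim,
    status = status
  )
  list(record = record, state = state, stats = stats)
}
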