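# Constant-velocity Kalman filter used to carry a marker through occlusion.
# State (u, v, du, dv) in pixels and pixels/frame; position-only
# observations; diagonal process/measurement noise.

#' Tracking parameters
#'
#' @param tau_drift Drift gate (pixels): the maximum displacement an
#'   occlusion estimate may accumulate away from the last confirmed
#'   detection (default 50). When the filter prediction exceeds it, the
#'   estimate is clamped to the gate boundary along the prediction
#'   direction.
#' @param roi_scale Search-window scale `k`: the region of interest is a
#'   square of side `k` times the marker's reference bounding-box diagonal
#'   (default 3).
#' @param process_noise Diagonal process noise `q` (default 1e-2).
#' @param measurement_noise Diagonal measurement noise `r` (default 1).
#' @param max_lost_frames Consecutive undetected frames after which the
#'   track status becomes `"lost"` (default 75, i.e. 3 s at 25 fps).
#' @return List of class `mm_track_params`.
#' @export
track_params <- function(tau_drift = 50, roi_scale = 3,
                         process_noise = 1e-2, measurement_noise = 1,
                         max_lost_frames = 75) {
  stopifnot(tau_drift > 0, roi_scale > 0, process_noise > 0,
            measurement_noise > 0, max_lost_frames > 0)
  structure(
    list(tau_drift = tau_drift, roi_scale = roi_scale,
         process_noise = process_noise,
         measurement_noise = measurement_noise,
         max_lost_frames = max_lost_frames),
    class = "mm_track_params"
  )
}

#' Create a track state for a marker
#'
#' @param marker_id Marker identifier.
#' @param px Initial pixel position `(u, v)`.
#' @param params [track_params()].
#' @return List of class `mm_track_state` with the Kalman state vector
#'   `(u, v, du, dv)`, covariance, last detected position, frames since the
#'   last detection and a status flag.
#' @export
new_track_state <- function(marker_id, px, params = track_params()) {
  structure(
    list(marker_id = marker_id,
         x = c(px[1], px[2], 0, 0),
         P = diag(c(10, 10, 10, 10)),
         last_detected_px = c(px[1], px[2]),
         frames_since_detection = 0L,
         status = "detected",
         initialized = TRUE,
         q = params$process_noise,
         r = params$measurement_noise),
    class = "mm_track_state"
  )
}

kalman_F <- matrix(c(1, 0, 0, 0,
                     0, 1, 0, 0,
                     1, 0, 1, 0,
                     0, 1, 0, 1), 4, 4)  # column-major: x' = x + v
kalman_H <- matrix(c(1, 0, 0, 1, 0, 0, 0, 0), 2, 4)

#' Kalman prediction step
#'
#' Constant-velocity transition over one frame: position advances by the
#' velocity estimate and the covariance grows by the process noise.
#'
#' @param state [new_track_state()] object.
#' @return Predicted state.
#' @export
kalman_predict <- function(state) {
  if (is.null(state$initialized) || !state$initialized) {
    abort("kalman_predict(): uninitialized track state")
  }
  state$x <- as.vector(kalman_F %*% state$x)
  state$P <- kalman_F %*% state$P %*% t(kalman_F) + diag(state$q, 4)
  state$P <- (state$P + t(state$P)) / 2
  state
}

#' Kalman correction step
#'
#' Standard linear update against a position observation; resets the
#' occlusion counter and the last-detected position.
#'
#' @param state Predicted state.
#' @param measurement Observed pixel position `(u, v)`.
#' @return Corrected state with `status = "detected"`.
#' @export
kalman_update <- function(state, measurement) {
  if (any(!is.finite(measurement)) || length(measurement) != 2) {
    abort("kalman_update(): non-finite measurement")
  }
  H <- kalman_H
  S <- H %*% state$P %*% t(H) + diag(state$r, 2)
  K <- state$P %*% t(H) %*% solve(S)
  innov <- measurement - as.vector(H %*% state$x)
  state$x <- state$x + as.vector(K %*% innov)
  state$P <- (diag(4) - K %*% H) %*% state$P
  state$P <- (state$P + t(state$P)) / 2
  state$last_detected_px <- c(measurement[1], measurement[2])
  state$frames_since_detection <- 0L
  state$status <- "detected"
  state
}

#' Region-of-interest search window
#'
#' Square window of side `k` times the marker's reference bounding-box
#' diagonal, centered at the last known position and clipped to the image.
#'
#' @param last_px Last known pixel position `(u, v)`.
#' @param marker Marker spec carrying `ref_diag` (set at registration).
#' @param k Window scale.
#' @param image_size `(width, height)` in pixels.
#' @return List `(x0, x1, y0, y1)` of 0-based inclusive pixel bounds.
#' @export
roi_window <- function(last_px, marker, k, image_size) {
  stopifnot(all(is.finite(last_px)))
  diag_px <- marker$ref_diag %||% 20
  half <- max(1, k * diag_px / 2)
  x0 <- max(0, floor(last_px[1] - half))
  x1 <- min(image_size[1] - 1, ceiling(last_px[1] + half))
  y0 <- max(0, floor(last_px[2] - half))
  y1 <- min(image_size[2] - 1, ceiling(last_px[2] + half))
  list(x0 = x0, x1 = x1, y0 = y0, y1 = y1)
}
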