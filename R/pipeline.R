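# End-to-end pipeline: synchronized stream -> registration -> per-frame
# detection/tracking -> back-projection -> joint angles, plus evaluation
# against ground truth.

#' Generate a synthetic dataset (pipeline front door)
#'
#' Thin wrapper around [generate_dataset()] using the default articulated
#' scene and motion when none are supplied.
#'
#' @param out_dir Output directory.
#' @param n_frames Number of frames (default 100).
#' @param scene [scene_spec()] (default articulated 12-marker scene).
#' @param script [motion_script()] (default 60-120 degree sinusoids with
#'   stepped 0.9-1.1 lighting and 2/255 pixel noise).
#' @param seed RNG seed (overrides the scene seed).
#' @param depth_offset_ms Depth clock offset (scalar or per frame).
#' @return Invisibly the [generate_dataset()] result.
#' @export
mm_synth <- function(out_dir, n_frames = 100, scene = NULL, script = NULL,
                     seed = 1L, depth_offset_ms = 0) {
  scene <- scene %||% scene_spec(seed = seed)
  scene$seed <- as.integer(seed)
  script <- script %||%
    motion_script(lighting = lighting_schedule(n_frames))
  generate_dataset(scene, script, n_frames, out_dir,
                   depth_offset_ms = depth_offset_ms)
}

#' Run detection, tracking and angle computation on a dataset
#'
#' Reads and synchronizes the frame stream, registers every marker on the
#' first retained frame at its configured initial position, then runs the
#' per-frame tracking state machine; detected/estimated pixel positions are
#' back-projected through the depth channel and the pinhole model, and
#' joint angles are computed for every configured triple. Deterministic
#' given inputs and configuration.
#'
#' @param dataset_dir Dataset directory (`color/`, `depth/`,
#'   `timestamps.csv`, `config.yaml`).
#' @param config Optional [run_config()]; default reads
#'   `config.yaml` from `dataset_dir`.
#' @param out_dir Optional directory to write `detections.csv` and
#'   `angles.csv`.
#' @param angle_mode `"3d"` (default) or `"sagittal"`.
#' @param detect_only Skip angle computation.
#' @param quiet Suppress progress messages.
#' @return List of class `mm_result`: `detections` and `angles` tibbles,
#'   `log` (dropped frames, status transitions, drift-gate events),
#'   `config`.
#' @export
mm_track <- function(dataset_dir, config = NULL, out_dir = NULL,
                     angle_mode = c("3d", "sagittal"), detect_only = FALSE,
                     quiet = TRUE) {
  angle_mode <- match.arg(angle_mode)
  config <- config %||% read_run_config(file.path(dataset_dir, "config.yaml"))
  manifest <- read_frame_stream(
    file.path(dataset_dir, "color"), file.path(dataset_dir, "depth"),
    file.path(dataset_dir, "timestamps.csv"),
    params = config$sync, quiet = quiet
  )
  if (nrow(manifest) == 0) abort("mm_track(): no synchronized frames")
  dropped <- attr(manifest, "dropped_indices")
  dparams <- config$detection_params
  tparams <- config$track_params

  # registration on the first retained frame
  first_pair <- read_frame_pair(manifest[1, ])
  markers <- config$markers
  states <- list(); stats <- list()
  for (i in seq_along(markers)) {
    reg <- register_marker(first_pair$color, markers[[i]], dparams)
    markers[[i]] <- reg$marker
    stats[[markers[[i]]$id]] <- reg$stats
    states[[markers[[i]]$id]] <- new_track_state(markers[[i]]$id,
                                                 reg$center, tparams)
  }

  n_m <- length(markers)
  det_rows <- vector("list", nrow(manifest) * n_m)
  log_rows <- list()
  prev_status <- setNames(rep("detected", n_m),
                          vapply(markers, `[[`, "", "id"))
  for (f in seq_len(nrow(manifest))) {
    pair <- if (f == 1) first_pair else read_frame_pair(manifest[f, ])
    hsv_full <- NULL
    need_full <- FALSE
    for (i in seq_along(markers)) {
      id <- markers[[i]]$id
      if (is.null(hsv_full) && (need_full || states[[id]]$status != "detected")) {
        hsv_full <- rgb_to_hsv180(pair$color)
      }
      step <- track_frame(pair, markers[[i]], states[[id]], stats[[id]],
                          dparams, tparams, hsv_full = hsv_full)
      states[[id]] <- step$state
      stats[[id]] <- step$stats
      rec <- step$record
      if (rec$status != prev_status[[id]]) {
        log_rows[[length(log_rows) + 1]] <- tibble(
          frame_index = pair$frame_index, marker_id = id,
          event = paste0(prev_status[[id]], "->", rec$status)
        )
        prev_status[[id]] <- rec$status
      }
      if (rec$status != "detected") need_full <- TRUE
      z <- sample_depth(pair$depth, c(rec$u_px, rec$v_px))
      xyz <- if (is.na(z)) c(NA_real_, NA_real_, NA_real_) else
        backproject(c(rec$u_px, rec$v_px), z, config$camera)
      rec$x_mm <- xyz[1]; rec$y_mm <- xyz[2]; rec$z_mm <- xyz[3]
      det_rows[[(f - 1) * n_m + i]] <- rec
    }
  }
  detections <- dplyr::bind_rows(det_rows)[, detection_cols]
  angles <- if (detect_only) {
    tibble(frame_index = integer(), joint_name = character(),
           theta_deg = numeric())
  } else {
    compute_angles(detections, config$angle_joints, mode = angle_mode)
  }
  result <- structure(
    list(detections = detections, angles = angles,
         log = list(dropped_frames = dropped,
                    transitions = dplyr::bind_rows(log_rows)),
         config = config),
    class = "mm_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_detections(detections, file.path(out_dir, "detections.csv"))
    write_angles(angles, file.path(out_dir, "angles.csv"))
  }
  result
}

#' Evaluate pipeline output against ground truth
#'
#' Computes the average joint position error (AJPE, mm), the mean absolute
#' angle error (degrees) and frame coverage fractions.
#'
#' @param detections Detections tibble (with `x_mm`, `y_mm`, `z_mm`).
#' @param angles Angles tibble.
#' @param truth_markers Ground-truth marker tibble (`frame_index`,
#'   `marker_id`, `x_mm`, `y_mm`, `z_mm`).
#' @param truth_angles Ground-truth angle tibble.
#' @return Object of class `mm_eval` with `per_marker`, `per_joint`,
#'   `ajpe_mm`, `mean_angle_error_deg`, `coverage`.
#' @export
mm_evaluate <- function(detections, angles, truth_markers, truth_angles) {
  jpe <- joint_position_error(detections, truth_markers)
  ang <- if (nrow(angles) > 0 && nrow(truth_angles) > 0) {
    mean_angle_error(angles, truth_angles)
  } else {
    list(per_joint = tibble(joint_name = character(),
                            mean_error_deg = numeric(),
                            n_frames = integer(), n_missing = integer()),
         mean_angle_error_deg = NA_real_)
  }
  coverage <- list(
    detected_fraction = mean(detections$status == "detected"),
    marker_frames = sum(jpe$per_marker$n_frames),
    marker_missing = sum(jpe$per_marker$n_missing),
    angle_frames = sum(ang$per_joint$n_frames),
    angle_missing = sum(ang$per_joint$n_missing)
  )
  structure(
    list(per_marker = jpe$per_marker, per_joint = ang$per_joint,
         ajpe_mm = jpe$ajpe_mm,
         mean_angle_error_deg = ang$mean_angle_error_deg,
         coverage = coverage),
    class = "mm_eval"
  )
}

#' Evaluate a tracked run directly from directories
#'
#' @param result `mm_result` from [mm_track()], or a directory containing
#'   `detections.csv` and `angles.csv`.
#' @param truth_dir Directory containing `ground_truth_markers.csv` and
#'   `ground_truth_angles.csv`.
#' @return `mm_eval` object.
#' @export
mm_evaluate_dirs <- function(result, truth_dir) {
  if (is.character(result)) {
    detections <- read_detections(file.path(result, "detections.csv"))
    angles <- read_angles(file.path(result, "angles.csv"))
  } else {
    detections <- result$detections
    angles <- result$angles
  }
  truth_markers <- readr::read_csv(
    file.path(truth_dir, "ground_truth_markers.csv"), show_col_types = FALSE)
  truth_angles <- readr::read_csv(
    file.path(truth_dir, "ground_truth_angles.csv"), show_col_types = FALSE)
  mm_evaluate(detections, angles, truth_markers, truth_angles)
}

#' @export
print.mm_eval <- function(x, ...) {
  cat("Marker tracking evaluation\n")
  cat(sprintf("  AJPE: %.3f mm over %d markers\n",
              x$ajpe_mm, nrow(x$per_marker)))
  if (!is.na(x$mean_angle_error_deg)) {
    cat(sprintf("  Mean angle error: %.3f deg over %d joints\n",
                x$mean_angle_error_deg, nrow(x$per_joint)))
  }
  cat(sprintf("  Detected fraction: %.3f\n", x$coverage$detected_fraction))
  invisible(x)
}

#' Tidy an evaluation: one row per marker and per joint
#' @param x `mm_eval` object.
#' @param ... Unused.
#' @return Tibble with `term`, `metric`, `estimate`, `n_frames`,
#'   `n_missing`.
#' @export
tidy.mm_eval <- function(x, ...) {
  dplyr::bind_rows(
    x$per_marker |>
      dplyr::transmute(term = .data$marker_id, metric = "position_error_mm",
                       estimate = .data$mean_error_mm,
                       n_frames = .data$n_frames, n_missing = .data$n_missing),
    x$per_joint |>
      dplyr::transmute(term = .data$joint_name, metric = "angle_error_deg",
                       estimate = .data$mean_error_deg,
                       n_frames = .data$n_frames, n_missing = .data$n_missing)
  )
}

#' One-row evaluation summary
#' @param x `mm_eval` object.
#' @param ... Unused.
#' @return One-row tibble with `ajpe_mm`, `mean_angle_error_deg`,
#'   `detected_fraction`.
#' @export
glance.mm_eval <- function(x, ...) {
  tibble(ajpe_mm = x$ajpe_mm,
         mean_angle_error_deg = x$mean_angle_error_deg,
         detected_fraction = x$coverage$detected_fraction)
}

#' Write an evaluation report as JSON
#' @param eval_obj `mm_eval` object.
#' @param path Output path.
#' @export
write_eval_report <- function(eval_obj, path) {
  jsonlite::write_json(
    list(
      ajpe_mm = eval_obj$ajpe_mm,
      mean_angle_error_deg = eval_obj$mean_angle_error_deg,
      per_marker = eval_obj$per_marker,
      per_joint = eval_obj$per_joint,
      coverage = eval_obj$coverage
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
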