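# Shared fixtures: small synthetic scenes built in code.

# A single-marker test scene (magenta circle) at 1 m depth, 640x480.
one_marker_scene <- function(seed = 1L, marker_size_mm = 35) {
  scene_spec(
    camera = camera_model(800, 800, 320, 240),
    image_size = c(640, 480),
    table_depth_mm = 1000,
    marker_z_offset_mm = 0,
    marker_size_mm = marker_size_mm,
    layout = list(list(id = "p0", joint_label = "Probe", color_name = "magenta",
                       shape = "circle")),
    skeleton = NULL,
    static_positions = local({
      p <- list(Probe = c(0, 0))
      attr(p, "angle_joints") <- list()
      p
    }),
    seed = seed
  )
}

# Write a dataset with explicit per-frame marker positions (body-plane mm),
# bypassing the forward-kinematics layer; exercises render_frame and the
# io formats directly. positions: list over frames of named lists
# (joint_label -> c(x, y)).
write_custom_dataset <- function(dir, scene, positions,
                                 occluders = function(t) list(),
                                 lighting = function(t) 1,
                                 noise_sd = 0,
                                 depth_offset_ms = 0) {
  dir.create(file.path(dir, "color"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "depth"), recursive = TRUE, showWarnings = FALSE)
  set.seed(scene$seed)
  z <- scene$table_depth_mm - scene$marker_z_offset_mm
  ids <- vapply(scene$layout, `[[`, "", "id")
  labels <- vapply(scene$layout, `[[`, "", "joint_label")
  n_frames <- length(positions)
  gt <- vector("list", n_frames)
  for (t in seq_len(n_frames) - 1L) {
    body <- do.call(rbind, positions[[t + 1]][labels])
    pos <- cbind(body[, 1], body[, 2], z)
    rownames(pos) <- ids
    fr <- render_frame(pos, scene, lighting_factor = lighting(t),
                       occluders = occluders(t), noise_sd = noise_sd)
    write_color_frame(fr$color,
                      file.path(dir, "color", sprintf("color_%06d.png", t)))
    write_depth_frame(fr$depth,
                      file.path(dir, "depth", sprintf("depth_%06d.tif", t)))
    gt[[t + 1]] <- tibble::tibble(
      frame_index = t, marker_id = ids,
      u_px = fr$centers_px[, 1], v_px = fr$centers_px[, 2],
      x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3]
    )
  }
  gt <- dplyr::bind_rows(gt)
  color_ts <- (seq_len(n_frames) - 1) * 40
  readr::write_csv(
    tibble::tibble(frame_index = seq_len(n_frames) - 1L,
                   color_ts_ms = color_ts,
                   depth_ts_ms = color_ts + rep_len(depth_offset_ms, n_frames)),
    file.path(dir, "timestamps.csv"))
  readr::write_csv(gt, file.path(dir, "ground_truth_markers.csv"))
  first <- gt[gt$frame_index == 0, ]
  markers <- lapply(scene$layout, function(lay) {
    row <- first[first$marker_id == lay$id, ]
    marker_spec(id = lay$id, joint_label = lay$joint_label,
                color_name = lay$color_name, shape = lay$shape,
                init_px = c(round(row$u_px), round(row$v_px)))
  })
  config <- run_config(markers = markers, angle_joints = list(),
                       camera = scene$camera)
  write_run_config(config, file.path(dir, "config.yaml"))
  list(dir = dir, config = config, ground_truth = gt)
}

# Static script (no articulation, no noise) for canvas-style scenes.
static_script <- function(noise_sd = 0) {
  motion_script(joints = default_joint_trajectories(amplitude_deg = 0),
                noise_sd = noise_sd)
}

# Memoised heavy fixtures shared between tests within one run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}
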