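# Synthetic RGB-D scene generator with full ground truth.
#
# Emulates the overhead recording rig (camera ~2 m above the table, optical
# axis perpendicular to it): a lying articulated figure carries 12 colored
# geometric markers on shoulders, elbows, wrists, hips, knees and ankles;
# joint angles follow sinusoidal trajectories through planar forward
# kinematics; frames are rendered with white-bordered colored shapes on a
# uniform table, a registered depth channel, optional occluder rectangles,
# multiplicative lighting changes and additive pixel noise. Ground truth
# (marker pixel centers, 3D positions, joint angles) is exact by
# construction.

#' Synthetic scene specification
#'
#' @param camera [camera_model()]; default fx = fy = 800 px with the
#'   principal point at the image center.
#' @param image_size `(width, height)` in pixels (default 960 x 540).
#' @param background Background RGB in `[0, 1]` (default mid gray).
#' @param table_depth_mm Depth of the table plane (default 2000, the
#'   camera-to-table distance of the rig).
#' @param marker_z_offset_mm Height of the markers above the table
#'   (default 80, roughly body thickness).
#' @param marker_size_mm Physical marker diameter (default 45, which
#'   projects to about 18 px at the table).
#' @param occluder_depth_mm Depth assigned to occluder pixels (default 600,
#'   an object between camera and patient).
#' @param layout Marker layout: list of lists `(id, joint_label,
#'   color_name, shape)`; default [default_marker_layout()].
#' @param skeleton [default_skeleton()] or compatible list.
#' @param static_positions Optional named list of fixed body-plane `(x, y)`
#'   positions in mm (one per marker id); overrides the skeleton (used by
#'   [canvas_scene()]).
#' @param seed Integer RNG seed for rendering noise.
#' @return List of class `mm_scene`.
#' @export
scene_spec <- function(camera = camera_model(800, 800, 480, 270),
                       image_size = c(960, 540),
                       background = c(0.47, 0.47, 0.47),
                       table_depth_mm = 2000,
                       marker_z_offset_mm = 80,
                       marker_size_mm = 45,
                       occluder_depth_mm = 600,
                       layout = default_marker_layout(),
                       skeleton = default_skeleton(),
                       static_positions = NULL,
                       seed = 1L) {
  stopifnot(table_depth_mm > 0, marker_size_mm > 0)
  structure(
    list(camera = camera, image_size = image_size, background = background,
         table_depth_mm = table_depth_mm,
         marker_z_offset_mm = marker_z_offset_mm,
         marker_size_mm = marker_size_mm,
         occluder_depth_mm = occluder_depth_mm,
         layout = layout, skeleton = skeleton,
         static_positions = static_positions, seed = as.integer(seed)),
    class = "mm_scene"
  )
}

#' Default 12-marker layout
#'
#' Markers `m0`..`m11` on shoulders, elbows, wrists, hips, knees and
#' ankles; each of the six colors is used twice, assigned so same-color
#' markers sit on distant body parts, with different shapes.
#'
#' @return List of marker layout entries.
#' @export
default_marker_layout <- function() {
  defs <- list(
    c("m0", "ShoulderR", "magenta", "circle"),
    c("m1", "ShoulderL", "red", "circle"),
    c("m2", "ElbowR", "green", "cross"),
    c("m3", "ElbowL", "yellow", "cross"),
    c("m4", "WristR", "blue", "triangle"),
    c("m5", "WristL", "cyan", "triangle"),
    c("m6", "HipR", "yellow", "bar"),
    c("m7", "HipL", "green", "bar"),
    c("m8", "KneeR", "cyan", "circle"),
    c("m9", "KneeL", "blue", "circle"),
    c("m10", "AnkleR", "red", "cross"),
    c("m11", "AnkleL", "magenta", "cross")
  )
  lapply(defs, function(d) {
    list(id = d[1], joint_label = d[2], color_name = d[3], shape = d[4])
  })
}

#' Default lying-pose skeleton
#'
#' Body-plane base points (mm; x rightwards across the table, y along the
#' body axis) for shoulders and hips, and limb segment lengths sized for a
#' small (pediatric) patient so the whole figure stays inside the frame.
#'
#' @return List with `bases` (named list of 2-vectors) and `lengths`.
#' @export
default_skeleton <- function() {
  list(
    bases = list(
      ShoulderR = c(-220, -260), ShoulderL = c(220, -260),
      HipR = c(-150, 160), HipL = c(150, 160)
    ),
    lengths = c(upper_arm = 170, forearm = 150, thigh = 190, shank = 170)
  )
}

#' Default angle-joint triples of the 12-marker layout
#'
#' The eight joints with clinically meaningful angles: shoulders, elbows,
#' hips and knees on both sides, each defined by the ordered marker triple
#' whose middle marker carries the angle.
#'
#' @return List of lists `(name, ids)`.
#' @export
default_angle_joints <- function() {
  list(
    list(name = "ShoulderR", ids = c("m2", "m0", "m6")),
    list(name = "ShoulderL", ids = c("m3", "m1", "m7")),
    list(name = "ElbowR", ids = c("m4", "m2", "m0")),
    list(name = "ElbowL", ids = c("m5", "m3", "m1")),
    list(name = "HipR", ids = c("m0", "m6", "m8")),
    list(name = "HipL", ids = c("m1", "m7", "m9")),
    list(name = "KneeR", ids = c("m6", "m8", "m10")),
    list(name = "KneeL", ids = c("m7", "m9", "m11"))
  )
}

#' Motion script
#'
#' @param joints Tibble with columns `joint`, `base_deg`, `amplitude_deg`,
#'   `freq_cpf` (cycles per frame), `phase_deg`; the scripted angle is
#'   `base + A * sin(2 pi f t + phase)`.
#' @param occlusions List of events `(marker_ids, start, duration, rect)`;
#'   `rect = (x0, x1, y0, y1)` pixels, drawn over frames
#'   `[start, start + duration - 1]`.
#' @param lighting List of events `(start, duration, factor)`; frames in
#'   range get their RGB multiplied by `factor`.
#' @param noise_sd Additive Gaussian pixel noise sigma on `[0, 1]` values
#'   (default `2/255`).
#' @return List of class `mm_motion_script`.
#' @export
motion_script <- function(joints = default_joint_trajectories(),
                          occlusions = list(), lighting = list(),
                          noise_sd = 2 / 255) {
  stopifnot(noise_sd >= 0)
  for (ev in occlusions) {
    if (ev$duration < 0) abort("motion_script(): occlusion duration < 0")
  }
  for (ev in lighting) {
    if (ev$factor <= 0) abort("motion_script(): brightness factor must be > 0")
  }
  lo <- joints$base_deg - joints$amplitude_deg
  hi <- joints$base_deg + joints$amplitude_deg
  if (any(lo <= 0) || any(hi >= 180)) {
    abort("motion_script(): impossible articulation, angles must stay in (0, 180)")
  }
  structure(list(joints = joints, occlusions = occlusions,
                 lighting = lighting, noise_sd = noise_sd),
            class = "mm_motion_script")
}

#' Default sinusoidal joint trajectories (60-120 degrees)
#'
#' All eight angle joints oscillate between 60 and 120 degrees around a
#' 90-degree base with a 50-frame period (2 s at 25 fps) and staggered
#' phases.
#'
#' @param amplitude_deg Oscillation amplitude (default 30).
#' @param freq_cpf Frequency in cycles/frame (default 0.02).
#' @return Tibble of per-joint trajectory parameters.
#' @export
default_joint_trajectories <- function(amplitude_deg = 30, freq_cpf = 0.02) {
  joints <- c("ShoulderR", "ShoulderL", "ElbowR", "ElbowL",
              "HipR", "HipL", "KneeR", "KneeL")
  tibble(
    joint = joints,
    base_deg = 90,
    amplitude_deg = amplitude_deg,
    freq_cpf = freq_cpf,
    phase_deg = seq(0, 315, by = 45)
  )
}

#' Lighting schedule covering a sequence with stepped brightness factors
#'
#' Splits `n_frames` into `length(factors)` equal blocks, one lighting
#' event per block.
#'
#' @param n_frames Number of frames.
#' @param factors Brightness factors (default `c(0.9, 1, 1.1)`).
#' @return List of lighting events for [motion_script()].
#' @export
lighting_schedule <- function(n_frames, factors = c(0.9, 1, 1.1)) {
  k <- length(factors)
  bounds <- floor(seq(0, n_frames, length.out = k + 1))
  purrr::map(seq_len(k), function(i) {
    list(start = bounds[i], duration = bounds[i + 1] - bounds[i],
         factor = factors[i])
  })
}

# Scripted angle of one joint at (0-based) frame t.
scripted_angle <- function(joints, joint, t) {
  row <- joints[joints$joint == joint, ]
  if (nrow(row) == 0) return(90)
  row$base_deg + row$amplitude_deg *
    sin(2 * pi * row$freq_cpf * t + row$phase_deg * pi / 180)
}

# Forward kinematics of the lying figure at one frame: returns a named
# matrix of body-plane (x, y) positions for all 12 joint labels.
pose_at <- function(skeleton, joints, t) {
  b <- skeleton$bases
  L <- skeleton$lengths
  out <- list(ShoulderR = b$ShoulderR, ShoulderL = b$ShoulderL,
              HipR = b$HipR, HipL = b$HipL)
  for (side in c("R", "L")) {
    s <- if (side == "R") 1 else -1
    sh <- b[[paste0("Shoulder", side)]]
    hp <- b[[paste0("Hip", side)]]
    ut <- (hp - sh) / sqrt(sum((hp - sh)^2))   # torso direction at shoulder
    a_dir <- as.vector(rotate2d(rbind(ut), s * scripted_angle(joints, paste0("Shoulder", side), t)))
    elbow <- sh + L[["upper_arm"]] * a_dir
    f_dir <- as.vector(rotate2d(rbind(-a_dir), s * scripted_angle(joints, paste0("Elbow", side), t)))
    wrist <- elbow + L[["forearm"]] * f_dir
    # legs articulate outward (abducted supine posture) so marker paths of
    # the two sides never cross
    t_dir <- as.vector(rotate2d(rbind(-ut), -s * scripted_angle(joints, paste0("Hip", side), t)))
    knee <- hp + L[["thigh"]] * t_dir
    s_dir <- as.vector(rotate2d(rbind(-t_dir), -s * scripted_angle(joints, paste0("Knee", side), t)))
    ankle <- knee + L[["shank"]] * s_dir
    out[[paste0("Elbow", side)]] <- elbow
    out[[paste0("Wrist", side)]] <- wrist
    out[[paste0("Knee", side)]] <- knee
    out[[paste0("Ankle", side)]] <- ankle
  }
  do.call(rbind, out)
}

#' Generate per-frame marker 3D positions from a motion script
#'
#' Applies the sinusoidal joint trajectories through planar forward
#' kinematics (all markers at a common height above the table, so planar
#' and 3D angles agree) and returns camera-coordinate marker positions and
#' the ground-truth angle series. Deterministic.
#'
#' @param script [motion_script()].
#' @param scene [scene_spec()].
#' @param n_frames Number of frames.
#' @return List with `positions` (list over frames of matrices
#'   `markers x 3`, rows named by marker id) and `angles` (tibble
#'   `frame_index`, `joint_name`, `theta_deg`).
#' @export
pose_sequence <- function(script, scene, n_frames) {
  z <- scene$table_depth_mm - scene$marker_z_offset_mm
  ids <- vapply(scene$layout, `[[`, "", "id")
  labels <- vapply(scene$layout, `[[`, "", "joint_label")
  angle_joints <- if (is.null(scene$static_positions)) {
    default_angle_joints()
  } else {
    attr(scene$static_positions, "angle_joints")
  }
  positions <- vector("list", n_frames)
  angle_rows <- vector("list", n_frames)
  for (t in seq_len(n_frames) - 1L) {
    body <- if (is.null(scene$static_positions)) {
      pose_at(scene$skeleton, script$joints, t)
    } else {
      do.call(rbind, scene$static_positions[labels])
    }
    pos <- cbind(body[labels, 1], body[labels, 2], z)
    rownames(pos) <- ids
    colnames(pos) <- c("x", "y", "z")
    positions[[t + 1]] <- pos
    if (length(angle_joints) > 0) {
      th <- vapply(angle_joints, function(jt) {
        p <- pos[jt$ids, , drop = FALSE]
        uv <- joint_vectors(p[1, ], p[2, ], p[3, ])
        angle_3d(uv$u, uv$v)
      }, numeric(1))
      angle_rows[[t + 1]] <- tibble(
        frame_index = t,
        joint_name = vapply(angle_joints, `[[`, "", "name"),
        theta_deg = th
      )
    }
  }
  list(positions = positions, angles = dplyr::bind_rows(angle_rows),
       angle_joints = angle_joints)
}

# Fill a polygon into image channels. poly in 0-based pixel coords.
fill_polygon <- function(color_img, depth_img, poly, rgb, depth_mm) {
  d <- dim(color_img)
  x0 <- max(0, floor(min(poly[, 1]))); x1 <- min(d[2] - 1, ceiling(max(poly[, 1])))
  y0 <- max(0, floor(min(poly[, 2]))); y1 <- min(d[1] - 1, ceiling(max(poly[, 2])))
  if (x1 < x0 || y1 < y0) return(list(color = color_img, depth = depth_img))
  xs <- x0:x1; ys <- y0:y1
  grid <- expand.grid(y = ys, x = xs)
  inside <- points_in_polygon(grid$x, grid$y, poly)
  if (!any(inside)) return(list(color = color_img, depth = depth_img))
  rows <- grid$y[inside] + 1L
  cols <- grid$x[inside] + 1L
  for (ch in 1:3) {
    idx <- cbind(rows, cols, ch)
    color_img[idx] <- rgb[ch]
  }
  depth_img[cbind(rows, cols)] <- depth_mm
  list(color = color_img, depth = depth_img)
}

#' Render one synthetic frame
#'
#' Draws every marker at its projected position -- a white border shape
#' under a colored shape, both scaled by the pinhole projection of the
#' physical marker size -- over a uniform table; the depth channel carries
#' the marker depth at marker pixels and the table depth elsewhere. Then
#' applies scheduled occluders (over both channels), the lighting factor
#' (multiplicative on RGB, which scales V and leaves hue/saturation
#' untouched), additive Gaussian noise, and 8-bit quantization so the
#' in-memory frame equals the PNG on disk.
#'
#' @param pos Matrix `markers x 3` of camera-coordinate positions (mm),
#'   rows named by marker id.
#' @param scene [scene_spec()].
#' @param lighting_factor Brightness multiplier.
#' @param occluders List of rectangles `(x0, x1, y0, y1)` in pixels.
#' @param noise_sd Gaussian noise sigma (uses the current RNG stream).
#' @return List with `color`, `depth`, and `centers_px` (matrix of true
#'   projected marker centers).
#' @export
render_frame <- function(pos, scene, lighting_factor = 1,
                         occluders = list(), noise_sd = 0) {
  w <- scene$image_size[1]; h <- scene$image_size[2]
  color <- array(rep(scene$background, each = w * h), dim = c(h, w, 3))
  depth <- matrix(as.integer(scene$table_depth_mm), h, w)
  centers <- matrix(NA_real_, nrow(pos), 2,
                    dimnames = list(rownames(pos), c("u", "v")))
  for (i in seq_len(nrow(pos))) {
    ctr <- project_point(pos[i, ], scene$camera)
    id <- rownames(pos)[i]
    if (ctr[1] < 0 || ctr[1] > w - 1 || ctr[2] < 0 || ctr[2] > h - 1) {
      abort(paste0("render_frame(): marker '", id, "' projects out of frame"))
    }
    centers[i, ] <- ctr
    lay <- scene$layout[[which(vapply(scene$layout, `[[`, "", "id") == id)]]
    size_px <- scene$marker_size_mm * scene$camera$fx / pos[i, 3]
    shape <- shape_template(lay$shape, size_px)
    border <- shape_template(lay$shape, size_px * 1.5)
    off <- function(p) cbind(p[, 1] + ctr[1], p[, 2] + ctr[2])
    res <- fill_polygon(color, depth, off(border), c(1, 1, 1), pos[i, 3])
    res <- fill_polygon(res$color, res$depth, off(shape),
                        marker_color_rgb(lay$color_name), pos[i, 3])
    color <- res$color; depth <- res$depth
  }
  if (lighting_factor != 1) {
    color <- pmin(pmax(color * lighting_factor, 0), 1)
  }
  for (rc in occluders) {
    rect_poly <- cbind(c(rc[1], rc[2], rc[2], rc[1]) + c(-0.5, 0.5, 0.5, -0.5),
                       c(rc[3], rc[3], rc[4], rc[4]) + c(-0.5, -0.5, 0.5, 0.5))
    res <- fill_polygon(color, depth, rect_poly, c(0.35, 0.35, 0.35),
                        scene$occluder_depth_mm)
    color <- res$color; depth <- res$depth
  }
  if (noise_sd > 0) {
    color <- pmin(pmax(color + rnorm(length(color), sd = noise_sd), 0), 1)
  }
  color <- round(color * 255) / 255
  list(color = color, depth = depth, centers_px = centers)
}

# Occluders/lighting active at 0-based frame t.
active_occluders <- function(script, t) {
  evs <- purrr::keep(script$occlusions, function(ev) {
    t >= ev$start && t < ev$start + ev$duration
  })
  lapply(evs, `[[`, "rect")
}

occluded_ids <- function(script, t) {
  unlist(lapply(purrr::keep(script$occlusions, function(ev) {
    t >= ev$start && t < ev$start + ev$duration
  }), `[[`, "marker_ids"))
}

lighting_at <- function(script, t) {
  for (ev in script$lighting) {
    if (t >= ev$start && t < ev$start + ev$duration) return(ev$factor)
  }
  1
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes the exact external formats the reader consumes -- color PNGs,
#' 16-bit depth TIFFs, the timestamps CSV (25 fps color clock, configurable
#' depth-clock offset to exercise the synchronization rule), an
#' auto-generated YAML run configuration (marker HSV gates, first-frame
#' initial positions, camera intrinsics) -- plus the ground-truth marker
#' and angle tables.
#'
#' @param scene [scene_spec()].
#' @param script [motion_script()].
#' @param n_frames Number of frames.
#' @param out_dir Output directory (created).
#' @param depth_offset_ms Depth-clock offset: scalar or per-frame vector.
#' @param fps Frame rate of the color clock (default 25).
#' @return Invisibly, a list with the dataset paths and the generated
#'   config.
#' @export
generate_dataset <- function(scene, script, n_frames, out_dir,
                             depth_offset_ms = 0, fps = 25) {
  dir.create(file.path(out_dir, "color"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "depth"), recursive = TRUE, showWarnings = FALSE)
  set.seed(scene$seed)
  seq_data <- pose_sequence(script, scene, n_frames)
  gt_markers <- vector("list", n_frames)
  for (t in seq_len(n_frames) - 1L) {
    pos <- seq_data$positions[[t + 1]]
    fr <- render_frame(pos, scene,
                       lighting_factor = lighting_at(script, t),
                       occluders = active_occluders(script, t),
                       noise_sd = script$noise_sd)
    write_color_frame(fr$color, file.path(out_dir, "color", color_frame_name(t)))
    write_depth_frame(fr$depth,
                      file.path(out_dir, "depth", sprintf("depth_%06d.tif", t)))
    gt_markers[[t + 1]] <- tibble(
      frame_index = t,
      marker_id = rownames(pos),
      u_px = fr$centers_px[, 1],
      v_px = fr$centers_px[, 2],
      x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
      occluded = rownames(pos) %in% occluded_ids(script, t)
    )
  }
  gt_markers <- dplyr::bind_rows(gt_markers)
  color_ts <- (seq_len(n_frames) - 1) * 1000 / fps
  depth_ts <- color_ts + rep_len(depth_offset_ms, n_frames)
  ts <- tibble(frame_index = seq_len(n_frames) - 1L,
               color_ts_ms = color_ts, depth_ts_ms = depth_ts)
  readr::write_csv(ts, file.path(out_dir, "timestamps.csv"))
  readr::write_csv(gt_markers, file.path(out_dir, "ground_truth_markers.csv"))
  readr::write_csv(seq_data$angles, file.path(out_dir, "ground_truth_angles.csv"))

  first <- gt_markers[gt_markers$frame_index == 0, ]
  markers <- lapply(scene$layout, function(lay) {
    row <- first[first$marker_id == lay$id, ]
    marker_spec(id = lay$id, joint_label = lay$joint_label,
                color_name = lay$color_name, shape = lay$shape,
                init_px = c(round(row$u_px), round(row$v_px)))
  })
  config <- run_config(markers = markers,
                       angle_joints = seq_data$angle_joints,
                       camera = scene$camera)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(list(
    dir = out_dir,
    config = config,
    config_file = file.path(out_dir, "config.yaml"),
    timestamps = file.path(out_dir, "timestamps.csv"),
    ground_truth_markers = file.path(out_dir, "ground_truth_markers.csv"),
    ground_truth_angles = file.path(out_dir, "ground_truth_angles.csv")
  ))
}

#' Canvas validation scene preset
#'
#' Three static markers on a plane forming a requested angle at the middle
#' marker -- the synthetic counterpart of laying an arm along angles drawn
#' on a table-mounted canvas. The markers sit at 1 m depth, the two arm
#' markers 220 mm from the vertex.
#'
#' @param angle_deg Requested angle in `(0, 180)`.
#' @param arm_mm Arm length in mm (default 220).
#' @param seed RNG seed.
#' @return [scene_spec()] whose ground-truth angle `canvas` equals
#'   `angle_deg` on every frame.
#' @export
canvas_scene <- function(angle_deg, arm_mm = 220, seed = 1L) {
  stopifnot(angle_deg > 0, angle_deg < 180)
  half <- angle_deg / 2 * pi / 180
  positions <- list(
    CanvasA = arm_mm * c(cos(half), -sin(half)),
    CanvasMid = c(0, 0),
    CanvasB = arm_mm * c(cos(half), sin(half))
  )
  attr(positions, "angle_joints") <-
    list(list(name = "canvas", ids = c("c0", "c1", "c2")))
  layout <- list(
    list(id = "c0", joint_label = "CanvasA", color_name = "magenta",
         shape = "circle"),
    list(id = "c1", joint_label = "CanvasMid", color_name = "green",
         shape = "circle"),
    list(id = "c2", joint_label = "CanvasB", color_name = "blue",
         shape = "circle")
  )
  scene_spec(
    camera = camera_model(800, 800, 320, 240),
    image_size = c(640, 480),
    table_depth_mm = 1000,
    marker_z_offset_mm = 0,
    marker_size_mm = 35,
    layout = layout,
    static_positions = positions,
    seed = seed
  )
}
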