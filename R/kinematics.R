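# Back-projection to 3D camera coordinates, joint angles, and the two
# evaluation metrics (average joint position error, mean absolute angle
# error).

#' Pinhole camera model
#'
#' @param fx,fy Focal lengths in pixels.
#' @param cx,cy Principal point in pixels.
#' @param depth_unit Millimetres per raw depth count (default 1).
#' @return List of class `mm_camera`.
#' @export
camera_model <- function(fx, fy, cx, cy, depth_unit = 1) {
  stopifnot(fx > 0, fy > 0, depth_unit > 0)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 depth_unit = depth_unit),
            class = "mm_camera")
}

#' Sample a depth value at a pixel
#'
#' Median of the 3x3 neighborhood around the (rounded) pixel, excluding
#' zeros (zero encodes "no reading"); `NA` if all nine values are zero.
#' Robust against single-pixel dropouts at marker borders.
#'
#' @param depth_image Integer matrix `[height, width]` of millimetres.
#' @param center_px Pixel position `(u, v)`, 0-based.
#' @return Depth in millimetres, or `NA_real_`.
#' @export
sample_depth <- function(depth_image, center_px) {
  d <- dim(depth_image)
  u <- round(center_px[1]); v <- round(center_px[2])
  if (u < 0 || u >= d[2] || v < 0 || v >= d[1]) return(NA_real_)
  rows <- max(1, v):min(d[1], v + 2)        # v-1..v+1 in 1-based rows
  cols <- max(1, u):min(d[2], u + 2)
  vals <- as.numeric(depth_image[rows, cols])
  vals <- vals[vals > 0]
  if (length(vals) == 0) return(NA_real_)
  median(vals)
}

#' Back-project a pixel with depth to 3D camera coordinates
#'
#' `X = (u - cx) * Z / fx`, `Y = (v - cy) * Z / fy`, `Z = depth`.
#'
#' @param px Pixel `(u, v)`.
#' @param depth Depth in millimetres (> 0).
#' @param cam [camera_model()].
#' @return Numeric `(x, y, z)` in millimetres.
#' @export
backproject <- function(px, depth, cam) {
  if (!is.finite(depth) || depth <= 0) {
    abort("backproject(): depth must be positive")
  }
  z <- depth * cam$depth_unit
  c(x = (px[1] - cam$cx) * z / cam$fx,
    y = (px[2] - cam$cy) * z / cam$fy,
    z = z)
}

#' Project a 3D camera-coordinate point to pixels
#'
#' Forward pinhole projection, the inverse of [backproject()].
#'
#' @param xyz Numeric `(x, y, z)` in millimetres, `z > 0`.
#' @param cam [camera_model()].
#' @return Pixel `(u, v)`.
#' @export
project_point <- function(xyz, cam) {
  if (xyz[3] <= 0) abort("project_point(): z must be positive")
  c(u = cam$fx * xyz[1] / xyz[3] + cam$cx,
    v = cam$fy * xyz[2] / xyz[3] + cam$cy)
}

#' Limb vectors at a joint
#'
#' For an ordered joint triple (i, j, k) with the angle measured at the
#' middle joint j: `u = l_j - l_i`, `v = l_j - l_k`.
#'
#' @param l_i,l_j,l_k Numeric `(x, y, z)` positions in millimetres.
#' @return List with vectors `u` and `v`.
#' @export
joint_vectors <- function(l_i, l_j, l_k) {
  list(u = as.numeric(l_j) - as.numeric(l_i),
       v = as.numeric(l_j) - as.numeric(l_k))
}

#' 3D angle between two limb vectors
#'
#' `theta = arccos(u . v / (|u| |v|))` in degrees; the cosine is clamped to
#' `[-1, 1]` against rounding so 0 and 180 degrees are reachable.
#'
#' @param u,v Numeric 3-vectors (non-zero).
#' @param joint Optional joint name used in the degenerate-vector error.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angle_3d <- function(u, v, joint = NULL) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort(paste0("angle_3d(): zero-length limb vector",
                 if (!is.null(joint)) paste0(" at joint '", joint, "'")))
  }
  ct <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Angle between limb vectors projected into a body plane
#'
#' Projects out the configured plane-normal axis and returns the 2D angle
#' of the projected vectors; with an overhead camera and a patient lying on
#' the table, normal `"z"` yields the sagittal-plane angle.
#'
#' @param u,v Numeric 3-vectors.
#' @param normal_axis Axis to project out: `"x"`, `"y"` or `"z"`.
#' @param joint Optional joint name for error messages.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angle_sagittal <- function(u, v, normal_axis = "z", joint = NULL) {
  ax <- match(normal_axis, c("x", "y", "z"))
  if (is.na(ax)) abort("angle_sagittal(): normal_axis must be x, y or z")
  up <- u; vp <- v
  up[ax] <- 0; vp[ax] <- 0
  if (sum(up^2) == 0 || sum(vp^2) == 0) {
    abort(paste0("angle_sagittal(): degenerate projected vector",
                 if (!is.null(joint)) paste0(" at joint '", joint, "'")))
  }
  angle_3d(up, vp, joint = joint)
}

#' Compute joint-angle series from a detections table
#'
#' Joins the three markers of each configured angle joint per frame and
#' computes the angle at the middle marker from the back-projected 3D
#' positions. Frames where any of the three markers has no valid 3D
#' position yield a row with `theta_deg = NA` (explicitly missing, never
#' interpolated).
#'
#' @param detections Tibble with `frame_index`, `marker_id`, `x_mm`,
#'   `y_mm`, `z_mm`.
#' @param angle_joints List of joints, each a list with `name` and `ids`
#'   (ordered marker triple, angle at the middle id).
#' @param mode `"3d"` (default) or `"sagittal"`.
#' @param normal_axis Plane normal for `mode = "sagittal"`.
#' @return Tibble `frame_index`, `joint_name`, `theta_deg`.
#' @export
compute_angles <- function(detections, angle_joints, mode = c("3d", "sagittal"),
                           normal_axis = "z") {
  mode <- match.arg(mode)
  if (length(angle_joints) == 0) {
    return(tibble(frame_index = integer(), joint_name = character(),
                  theta_deg = numeric()))
  }
  frames <- sort(unique(detections$frame_index))
  pos <- detections |>
    dplyr::select("frame_index", "marker_id", "x_mm", "y_mm", "z_mm")
  key <- paste(pos$frame_index, pos$marker_id, sep = "\r")
  lookup <- split(seq_len(nrow(pos)), key)
  rows <- purrr::map(angle_joints, function(jt) {
    ids <- jt$ids
    theta <- vapply(frames, function(fr) {
      p <- lapply(ids, function(id) {
        i <- lookup[[paste(fr, id, sep = "\r")]]
        if (is.null(i)) return(NULL)
        v <- c(pos$x_mm[i[1]], pos$y_mm[i[1]], pos$z_mm[i[1]])
        if (anyNA(v)) NULL else v
      })
      if (any(vapply(p, is.null, logical(1)))) return(NA_real_)
      uv <- joint_vectors(p[[1]], p[[2]], p[[3]])
      if (mode == "3d") {
        angle_3d(uv$u, uv$v, joint = jt$name)
      } else {
        angle_sagittal(uv$u, uv$v, normal_axis = normal_axis,
                       joint = jt$name)
      }
    }, numeric(1))
    tibble(frame_index = frames, joint_name = jt$name, theta_deg = theta)
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$frame_index, .data$joint_name)
}

#' Average joint position error (AJPE)
#'
#' Per-marker mean Euclidean 3D distance between predicted and ground-truth
#' positions, and their mean over markers (the AJPE). Frames with a missing
#' prediction are excluded from the mean and counted.
#'
#' @param pred Tibble with `frame_index`, `marker_id`, `x_mm`, `y_mm`,
#'   `z_mm`.
#' @param truth Tibble with the same columns holding ground truth.
#' @return List with `per_marker` (tibble: `marker_id`, `mean_error_mm`,
#'   `n_frames`, `n_missing`) and `ajpe_mm`.
#' @export
joint_position_error <- function(pred, truth) {
  joined <- dplyr::inner_join(
    pred |> dplyr::select("frame_index", "marker_id",
                          px = "x_mm", py = "y_mm", pz = "z_mm"),
    truth |> dplyr::select("frame_index", "marker_id",
                           tx = "x_mm", ty = "y_mm", tz = "z_mm"),
    by = c("frame_index", "marker_id")
  )
  if (nrow(joined) == 0) {
    abort("joint_position_error(): no overlapping frames")
  }
  per_marker <- joined |>
    dplyr::mutate(
      missing = is.na(.data$px) | is.na(.data$py) | is.na(.data$pz),
      err = sqrt((.data$px - .data$tx)^2 + (.data$py - .data$ty)^2 +
                 (.data$pz - .data$tz)^2)
    ) |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(
      mean_error_mm = mean(.data$err[!.data$missing]),
      n_frames = sum(!.data$missing),
      n_missing = sum(.data$missing),
      .groups = "drop"
    )
  list(per_marker = per_marker,
       ajpe_mm = mean(per_marker$mean_error_mm))
}

#' Mean absolute angle error
#'
#' Per-joint mean absolute difference between predicted and ground-truth
#' angle series, and their mean over joints. Frames with a missing
#' prediction are excluded and counted.
#'
#' @param pred Tibble with `frame_index`, `joint_name`, `theta_deg`.
#' @param truth Tibble with the same columns holding ground truth.
#' @return List with `per_joint` (tibble: `joint_name`, `mean_error_deg`,
#'   `n_frames`, `n_missing`) and `mean_angle_error_deg`.
#' @export
mean_angle_error <- function(pred, truth) {
  joined <- dplyr::inner_join(
    pred |> dplyr::select("frame_index", "joint_name", p = "theta_deg"),
    truth |> dplyr::select("frame_index", "joint_name", t = "theta_deg"),
    by = c("frame_index", "joint_name")
  )
  if (nrow(joined) == 0) {
    abort("mean_angle_error(): no overlapping frames")
  }
  per_joint <- joined |>
    dplyr::mutate(missing = is.na(.data$p)) |>
    dplyr::group_by(.data$joint_name) |>
    dplyr::summarise(
      mean_error_deg = mean(abs(.data$p - .data$t)[!.data$missing]),
      n_frames = sum(!.data$missing),
      n_missing = sum(.data$missing),
      .groups = "drop"
    )
  list(per_joint = per_joint,
       mean_angle_error_deg = mean(per_joint$mean_error_deg))
}
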