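# Run configuration: marker registry, angle-joint triples, camera model and
# algorithm parameters, serialized as YAML.

#' Marker specification
#'
#' One physical marker: its identity, joint label, color gate, shape and
#' initial pixel position. The reference contour/area are filled in at
#' registration from the first frame (see [register_marker()]).
#'
#' @param id Unique marker id (string).
#' @param joint_label Anatomical label, e.g. `"ElbowR"`.
#' @param color_name One of magenta, red, green, yellow, blue, cyan.
#' @param shape One of circle, cross, triangle, bar.
#' @param init_px Initial pixel position `(u, v)`.
#' @param hsv_low,hsv_high HSV gate; defaults derived from `color_name`.
#' @return List of class `mm_marker_spec`.
#' @export
marker_spec <- function(id, joint_label, color_name,
                        shape = c("circle", "cross", "triangle", "bar"),
                        init_px,
                        hsv_low = NULL, hsv_high = NULL) {
  shape <- match.arg(shape)
  rng <- marker_hsv_range(color_name)
  structure(
    list(id = as.character(id), joint_label = joint_label,
         color_name = color_name, shape = shape,
         init_px = as.numeric(init_px),
         hsv_low = hsv_low %||% rng$low,
         hsv_high = hsv_high %||% rng$high,
         reference_contour = NULL, reference_area = NULL, ref_diag = NULL),
    class = "mm_marker_spec"
  )
}

#' Run configuration
#'
#' @param markers List of [marker_spec()] objects with unique ids.
#' @param angle_joints List of lists `(name, ids)`; `ids` is an ordered
#'   triple of distinct marker ids, the angle is measured at the middle id.
#' @param camera [camera_model()].
#' @param detection [detection_params()].
#' @param track [track_params()].
#' @param sync [sync_params()].
#' @return List of class `mm_config`.
#' @export
run_config <- function(markers, angle_joints, camera,
                       detection = detection_params(),
                       track = track_params(),
                       sync = sync_params()) {
  ids <- vapply(markers, `[[`, "", "id")
  if (anyDuplicated(ids)) abort("run_config(): marker ids must be unique")
  for (jt in angle_joints) {
    if (length(jt$ids) != 3 || anyDuplicated(jt$ids)) {
      abort(paste0("run_config(): angle joint '", jt$name,
                   "' needs 3 distinct marker ids"))
    }
    missing <- setdiff(jt$ids, ids)
    if (length(missing) > 0) {
      abort(paste0("run_config(): unknown marker id(s) in joint '",
                   jt$name, "': ", paste(missing, collapse = ", ")))
    }
  }
  structure(
    list(markers = markers, angle_joints = angle_joints, camera = camera,
         detection_params = detection, track_params = track, sync = sync),
    class = "mm_config"
  )
}

#' Write a run configuration to YAML
#' @param config [run_config()].
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  ser <- list(
    markers = lapply(config$markers, function(m) {
      list(id = m$id, joint_label = m$joint_label,
           color_name = m$color_name, shape = m$shape,
           init_px = as.numeric(m$init_px),
           hsv_low = as.numeric(m$hsv_low),
           hsv_high = as.numeric(m$hsv_high))
    }),
    angle_joints = lapply(config$angle_joints, function(jt) {
      list(name = jt$name, ids = as.character(jt$ids))
    }),
    camera = unclass(config$camera),
    detection_params = list(
      weights = as.list(config$detection_params$weights),
      combo_weights = as.numeric(config$detection_params$combo_weights),
      z_cutoff = config$detection_params$z_cutoff,
      tau_sim = config$detection_params$tau_sim,
      area_gate = as.list(config$detection_params$area_gate),
      init_window = config$detection_params$init_window,
      sigma_floors = as.list(config$detection_params$sigma_floors)
    ),
    track_params = unclass(config$track_params),
    sync = unclass(config$sync)
  )
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path written by [write_run_config()] (or hand-edited
#'   with the same field names).
#' @return [run_config()] object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("markers", "angle_joints", "camera", "detection_params",
             "track_params", "sync")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(paste0("read_run_config(): unknown config key(s): ",
                 paste(bad, collapse = ", ")))
  }
  markers <- lapply(raw$markers, function(m) {
    marker_spec(id = m$id, joint_label = m$joint_label,
                color_name = m$color_name, shape = m$shape,
                init_px = unlist(m$init_px),
                hsv_low = unlist(m$hsv_low), hsv_high = unlist(m$hsv_high))
  })
  dp <- raw$detection_params
  det <- if (is.null(dp)) detection_params() else detection_params(
    weights = unlist(dp$weights),
    combo_weights = unlist(dp$combo_weights),
    z_cutoff = dp$z_cutoff, tau_sim = dp$tau_sim,
    area_gate = unlist(dp$area_gate),
    init_window = dp$init_window,
    sigma_floors = if (is.null(dp$sigma_floors)) {
      c(area_frac = 0.10, convex = 0.05, center_frac = 0.5)
    } else {
      unlist(dp$sigma_floors)
    }
  )
  tp <- raw$track_params
  trk <- if (is.null(tp)) track_params() else track_params(
    tau_drift = tp$tau_drift, roi_scale = tp$roi_scale,
    process_noise = tp$process_noise,
    measurement_noise = tp$measurement_noise,
    max_lost_frames = tp$max_lost_frames
  )
  cam <- camera_model(fx = raw$camera$fx, fy = raw$camera$fy,
                      cx = raw$camera$cx, cy = raw$camera$cy,
                      depth_unit = raw$camera$depth_unit %||% 1)
  syn <- if (is.null(raw$sync)) sync_params() else
    sync_params(max_delta = raw$sync$max_delta)
  run_config(markers = markers,
             angle_joints = lapply(raw$angle_joints, function(jt) {
               list(name = jt$name, ids = unlist(jt$ids))
             }),
             camera = cam, detection = det, track = trk, sync = syn)
}
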