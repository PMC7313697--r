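# Frame stream I/O and timestamp synchronization.
#
# External formats: color frames are 8-bit RGB PNG; depth frames are
# single-channel 16-bit images holding millimetres (the generator writes
# TIFF, 16-bit PNG is accepted on input); timestamps are a CSV with columns
# frame_index, color_ts_ms, depth_ts_ms; run configuration is YAML
# mirroring the config field names.

#' Synchronization parameters
#'
#' @param max_delta Maximum tolerated color-depth timestamp difference in
#'   milliseconds; pairs above it are dropped. Default 6.25 ms, the lowest
#'   inter-sensor delay observed between the color and depth clocks of the
#'   sensor rig.
#' @return List of class `mm_sync_params`.
#' @export
sync_params <- function(max_delta = 6.25) {
  stopifnot(max_delta > 0)
  structure(list(max_delta = max_delta), class = "mm_sync_params")
}

#' Match color and depth timestamps
#'
#' Each color timestamp is matched (in temporal order) to the nearest
#' not-yet-used depth timestamp; pairs whose absolute difference exceeds
#' `max_delta` are dropped. Retained pairs preserve temporal order and each
#' depth frame is used at most once. Running the matcher on its own output
#' changes nothing (idempotence).
#'
#' @param color_ts,depth_ts Monotone non-decreasing timestamp vectors (ms).
#' @param params [sync_params()].
#' @return Tibble with 0-based `color_idx`, `depth_idx` and `delta_ms`;
#'   zero rows for empty input.
#' @export
synchronize <- function(color_ts, depth_ts, params = sync_params()) {
  if (length(color_ts) == 0 || length(depth_ts) == 0) {
    return(tibble(color_idx = integer(), depth_idx = integer(),
                  delta_ms = numeric()))
  }
  if (is.unsorted(color_ts) || is.unsorted(depth_ts)) {
    abort("synchronize(): non-monotone timestamps signal a corrupt stream")
  }
  used <- logical(length(depth_ts))
  ci <- integer(); di <- integer(); dd <- numeric()
  last_depth <- 0L
  for (i in seq_along(color_ts)) {
    free <- which(!used)
    if (length(free) == 0) break
    j <- free[which.min(abs(depth_ts[free] - color_ts[i]))]
    delta <- abs(depth_ts[j] - color_ts[i])
    if (delta <= params$max_delta && j > last_depth) {
      used[j] <- TRUE
      ci <- c(ci, i); di <- c(di, j); dd <- c(dd, delta)
      last_depth <- j
    }
  }
  tibble(color_idx = ci - 1L, depth_idx = di - 1L, delta_ms = dd)
}

# --- frame files -----------------------------------------------------------

color_frame_name <- function(i) sprintf("color_%06d.png", i)

depth_frame_candidates <- function(i) {
  sprintf(c("depth_%06d.tif", "depth_%06d.tiff", "depth_%06d.png"), i)
}

#' Write a color frame (8-bit RGB PNG)
#' @param image `[height, width, 3]` array in `[0, 1]`.
#' @param path Output path.
#' @export
write_color_frame <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Read a color frame
#' @param path PNG path.
#' @return `[height, width, 3]` array in `[0, 1]`.
#' @export
read_color_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) abort(paste0("color frame not 3-channel: ", path))
  img[, , 1:3, drop = FALSE]
}

#' Write a depth frame (single-channel 16-bit TIFF, millimetres)
#' @param depth Integer matrix of millimetres (0 = no reading).
#' @param path Output path (`.tif`).
#' @export
write_depth_frame <- function(depth, path) {
  if (any(depth < 0) || any(depth > 65535)) {
    abort("write_depth_frame(): depth must be within 0..65535 mm")
  }
  tiff::writeTIFF(depth / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read a depth frame (16-bit TIFF or PNG, millimetres)
#' @param path Image path.
#' @return Integer matrix of millimetres.
#' @export
read_depth_frame <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 16) {
      abort(paste0("depth frame is not 16-bit: ", path))
    }
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(matrix(as.integer(round(img * 65535)), nrow(img), ncol(img)))
  }
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' Read and synchronize a frame stream
#'
#' Reads the timestamp table, applies the synchronization rule, verifies
#' that every retained frame file exists, and returns a manifest of
#' synchronized frame pairs in index order. Dropped frame indices are
#' reported with a message and attached as an attribute.
#'
#' @param color_dir,depth_dir Directories of index-named frames.
#' @param timestamps Path to the timestamps CSV
#'   (`frame_index,color_ts_ms,depth_ts_ms`).
#' @param params [sync_params()].
#' @param quiet Suppress the dropped-frames message.
#' @return Tibble manifest (`frame_index`, `color_file`, `depth_file`,
#'   `color_ts_ms`, `depth_ts_ms`, `delta_ms`) with attribute
#'   `dropped_indices`; read individual pairs with [read_frame_pair()].
#' @export
read_frame_stream <- function(color_dir, depth_dir, timestamps,
                              params = sync_params(), quiet = FALSE) {
  ts <- readr::read_csv(timestamps, show_col_types = FALSE)
  req <- c("frame_index", "color_ts_ms", "depth_ts_ms")
  if (!all(req %in% names(ts))) {
    abort("read_frame_stream(): timestamps CSV needs frame_index, color_ts_ms, depth_ts_ms")
  }
  ts <- dplyr::arrange(ts, .data$frame_index)
  pairs <- synchronize(ts$color_ts_ms, ts$depth_ts_ms, params)
  dropped <- setdiff(ts$frame_index, ts$frame_index[pairs$color_idx + 1L])
  if (!quiet && length(dropped) > 0) {
    inform(paste0("dropped ", length(dropped), " unsynchronized frame(s): ",
                  paste(dropped, collapse = ", ")))
  }
  color_file <- file.path(color_dir,
                          color_frame_name(ts$frame_index[pairs$color_idx + 1L]))
  depth_file <- vapply(ts$frame_index[pairs$depth_idx + 1L], function(i) {
    cand <- file.path(depth_dir, depth_frame_candidates(i))
    hit <- cand[file.exists(cand)]
    if (length(hit) == 0) {
      abort(paste0("read_frame_stream(): missing depth frame for index ", i))
    }
    hit[1]
  }, character(1))
  missing_color <- !file.exists(color_file)
  if (any(missing_color)) {
    abort(paste0("read_frame_stream(): missing color frame for index ",
                 paste(ts$frame_index[pairs$color_idx + 1L][missing_color],
                       collapse = ", ")))
  }
  manifest <- tibble(
    frame_index = ts$frame_index[pairs$color_idx + 1L],
    color_file = color_file,
    depth_file = depth_file,
    color_ts_ms = ts$color_ts_ms[pairs$color_idx + 1L],
    depth_ts_ms = ts$depth_ts_ms[pairs$depth_idx + 1L],
    delta_ms = pairs$delta_ms
  )
  attr(manifest, "dropped_indices") <- dropped
  manifest
}

#' Read one frame pair from a manifest row
#'
#' @param manifest_row One row of the manifest from [read_frame_stream()].
#' @return List (`frame_index`, `color`, `depth`, `color_ts`, `depth_ts`);
#'   errors if the depth dimensions do not match the color dimensions.
#' @export
read_frame_pair <- function(manifest_row) {
  color <- read_color_frame(manifest_row$color_file[[1]])
  depth <- read_depth_frame(manifest_row$depth_file[[1]])
  if (!identical(dim(depth), dim(color)[1:2])) {
    abort(paste0("frame ", manifest_row$frame_index[[1]],
                 ": depth dimensions differ from color (unregistered input?)"))
  }
  list(frame_index = manifest_row$frame_index[[1]],
       color = color, depth = depth,
       color_ts = manifest_row$color_ts_ms[[1]],
       depth_ts = manifest_row$depth_ts_ms[[1]])
}

# --- tabular outputs -------------------------------------------------------

detection_cols <- c("frame_index", "marker_id", "u_px", "v_px",
                    "x_mm", "y_mm", "z_mm", "similarity", "status")
angle_cols <- c("frame_index", "joint_name", "theta_deg")

#' Write a detections table
#'
#' Deterministic column order (`frame_index, marker_id, u_px, v_px, x_mm,
#' y_mm, z_mm, similarity, status`); rereading gives value-identical data.
#'
#' @param records Detections tibble.
#' @param path Output CSV path.
#' @export
write_detections <- function(records, path) {
  for (cl in setdiff(detection_cols, names(records))) {
    records[[cl]] <- if (cl == "status") NA_character_ else NA_real_
  }
  readr::write_csv(records[detection_cols], path)
  invisible(path)
}

#' Read a detections table written by [write_detections()]
#' @param path CSV path.
#' @return Tibble.
#' @export
read_detections <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    frame_index = readr::col_integer(),
    marker_id = readr::col_character(),
    u_px = readr::col_double(), v_px = readr::col_double(),
    x_mm = readr::col_double(), y_mm = readr::col_double(),
    z_mm = readr::col_double(),
    similarity = readr::col_double(),
    status = readr::col_character()
  ))
}

#' Write an angles table (`frame_index, joint_name, theta_deg`)
#' @param records Angles tibble.
#' @param path Output CSV path.
#' @export
write_angles <- function(records, path) {
  for (cl in setdiff(angle_cols, names(records))) {
    records[[cl]] <- NA_real_
  }
  readr::write_csv(records[angle_cols], path)
  invisible(path)
}

#' Read an angles table written by [write_angles()]
#' @param path CSV path.
#' @return Tibble.
#' @export
read_angles <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    frame_index = readr::col_integer(),
    joint_name = readr::col_character(),
    theta_deg = readr::col_double()
  ))
}
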