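# HSV color gating.

# Convert an [H, W, 3] color array in [0, 1] to HSV in the 8-bit dialect:
# H in [0, 180), S and V in [0, 255]. Returns a list of three [H, W]
# matrices. Achromatic pixels get hue 0.
rgb_to_hsv180 <- function(image) {
  d <- dim(image)
  stopifnot(length(d) == 3, d[3] >= 3)
  rgb <- rbind(
    as.vector(image[, , 1]),
    as.vector(image[, , 2]),
    as.vector(image[, , 3])
  )
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  h <- hsv[1, ] * 180
  h[is.na(h)] <- 0
  list(
    h = matrix(h, d[1], d[2]),
    s = matrix(hsv[2, ] * 255, d[1], d[2]),
    v = matrix(hsv[3, ] * 255, d[1], d[2])
  )
}

#' Binary mask of pixels inside an HSV range
#'
#' Gates a color frame by a per-channel HSV range in the 8-bit dialect
#' (`H` in `[0, 180)`, `S`, `V` in `[0, 255]`). A pixel is set iff every
#' channel lies inside its range. If `low[1] > high[1]` the hue range wraps
#' around 180, which is how red (hue near 0/179) is expressed.
#'
#' @param image Color array `[height, width, 3]` with values in `[0, 1]`,
#'   or a precomputed HSV list from the internal converter.
#' @param low,high Length-3 numeric HSV triples `(H, S, V)`.
#' @return Logical matrix `[height, width]`.
#' @export
mask_by_hsv <- function(image, low, high) {
  check_hsv_range(low, high)
  hsv <- if (is.list(image)) image else rgb_to_hsv180(image)
  h <- hsv$h; s <- hsv$s; v <- hsv$v
  hue_ok <- if (low[1] > high[1]) {
    h >= low[1] | h <= high[1]        # wrapped (red)
  } else {
    h >= low[1] & h <= high[1]
  }
  hue_ok & s >= low[2] & s <= high[2] & v >= low[3] & v <= high[3]
}

check_hsv_range <- function(low, high) {
  if (length(low) != 3 || length(high) != 3 ||
      !is.numeric(low) || !is.numeric(high) ||
      anyNA(low) || anyNA(high)) {
    abort("mask_by_hsv(): HSV range must be two numeric triples")
  }
  if (any(c(low[1], high[1]) < 0) || any(c(low[1], high[1]) >= 180.00001) ||
      any(c(low[2:3], high[2:3]) < 0) || any(c(low[2:3], high[2:3]) > 255)) {
    abort("mask_by_hsv(): HSV range outside H in [0,180), S/V in [0,255]")
  }
  if (low[2] > high[2] || low[3] > high[3]) {
    abort("mask_by_hsv(): S/V ranges must have low <= high")
  }
  invisible(TRUE)
}

# Nominal RGB of the six marker colors (rows in [0, 1]).
marker_color_rgb <- function(color_name) {
  tab <- list(
    magenta = c(1, 0, 1), red = c(1, 0, 0), green = c(0, 1, 0),
    yellow = c(1, 1, 0), blue = c(0, 0, 1), cyan = c(0, 1, 1)
  )
  val <- tab[[color_name]]
  if (is.null(val)) abort(paste0("unknown marker color: ", color_name))
  val
}

# Default HSV gating range for a marker color: hue center +/- 12 (wrapping
# for red), S in [120, 255], V in [60, 255]. Broad enough to survive the
# lighting variation the renderer applies, narrow enough to separate hues.
marker_hsv_range <- function(color_name) {
  centers <- c(magenta = 150, red = 0, green = 60,
               yellow = 30, blue = 120, cyan = 90)
  if (!color_name %in% names(centers)) {
    abort(paste0("unknown marker color: ", color_name))
  }
  ctr <- centers[[color_name]]
  lo_h <- (ctr - 12) %% 180
  hi_h <- (ctr + 12) %% 180
  list(low = c(lo_h, 120, 60), high = c(hi_h, 255, 255))
}
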