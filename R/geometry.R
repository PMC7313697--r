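# Planar geometry helpers shared by the detection and rendering code.
# Contours are n x 2 numeric matrices of (x, y) vertices, implicitly closed.

#' Signed polygon area (shoelace formula)
#'
#' @param poly n x 2 matrix of (x, y) vertices, implicitly closed.
#' @return Signed area; positive for counter-clockwise orientation in a
#'   y-down pixel coordinate system the sign is flipped, callers that need a
#'   magnitude should take `abs()`.
#' @keywords internal
shoelace_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Convex hull of a point set as a polygon
#'
#' @param pts n x 2 matrix of points.
#' @return m x 2 matrix of hull vertices in order.
#' @keywords internal
hull_polygon <- function(pts) {
  pts <- as.matrix(pts)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  pts[idx, , drop = FALSE]
}

#' Contour convexity
#'
#' The ratio `A / C` between the area of a contour and the area of its convex
#' hull. Convex contours fill their hull completely and score 1; concave
#' shapes (e.g. a cross) score below 1. Used as one of the four features of
#' the marker similarity model.
#'
#' @param contour n x 2 matrix of (x, y) vertices (at least 3 non-collinear).
#' @return Convexity ratio in `(0, 1]`.
#' @export
#' @examples
#' square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' convexity(square)  # 1
convexity <- function(contour) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) {
    abort("convexity(): contour needs at least 3 points")
  }
  a <- abs(shoelace_area(contour))
  h <- abs(shoelace_area(hull_polygon(contour)))
  if (h <= 0) {
    abort("convexity(): degenerate contour with zero hull area")
  }
  min(a / h, 1)
}

#' Generate a marker shape template contour
#'
#' Produces the outline polygon of one of the four marker shapes at a given
#' size, centered at the origin. Circles are approximated by a 64-gon; the
#' cross is a plus-sign of five squares; the bar is a 3:1 rectangle; the
#' triangle is equilateral.
#'
#' @param shape One of `"circle"`, `"cross"`, `"triangle"`, `"bar"`.
#' @param size Overall diameter/width in the output units (pixels or mm).
#' @return n x 2 matrix of (x, y) vertices.
#' @export
shape_template <- function(shape = c("circle", "cross", "triangle", "bar"),
                           size = 1) {
  shape <- match.arg(shape)
  r <- size / 2
  poly <- switch(shape,
    circle = {
      th <- seq(0, 2 * pi, length.out = 65)[-65]
      cbind(r * cos(th), r * sin(th))
    },
    cross = {
      # plus sign: arm width = size/3
      a <- size / 6
      cbind(
        c(-a, a, a, 3 * a, 3 * a, a, a, -a, -a, -3 * a, -3 * a, -a),
        c(-3 * a, -3 * a, -a, -a, a, a, 3 * a, 3 * a, a, a, -a, -a)
      )
    },
    triangle = {
      th <- pi / 2 + c(0, 2, 4) * pi / 3
      cbind(r * cos(th), r * sin(th))
    },
    bar = {
      h <- r / 3
      cbind(c(-r, r, r, -r), c(-h, -h, h, h))
    }
  )
  # center on the bounding box so the detected bounding-box center and the
  # nominal marker position coincide (matters for the triangle)
  poly[, 1] <- poly[, 1] - (max(poly[, 1]) + min(poly[, 1])) / 2
  poly[, 2] <- poly[, 2] - (max(poly[, 2]) + min(poly[, 2])) / 2
  poly
}

# Vectorized even-odd point-in-polygon test used by the renderer.
# px, py: coordinates of query points; poly: n x 2 polygon.
points_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# 2D rotation of row-vectors (degrees, counter-clockwise for y-up axes).
rotate2d <- function(pts, angle_deg) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  as.matrix(pts) %*% t(R)
}
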