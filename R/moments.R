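# Shape moments and Hu-invariant matching.
#
# Geometric moments of a closed polygon are computed exactly with Green's
# theorem: the polygon is decomposed into signed triangles (origin, P_i,
# P_{i+1}) and the monomial integral over each triangle has the closed form
#   \int\int_T x^p y^q dx dy = J * sum_{a,b} C(p,a) C(q,b)
#       x1^a x2^{p-a} y1^b y2^{q-b} * (a+b)! (p+q-a-b)! / (p+q+2)!
# with J = x1*y2 - x2*y1. This makes the seven Hu invariants exact for the
# polygon (no rasterization), which is what gives the similarity-transform
# invariance the shape matcher relies on.

# Raw geometric moment m_pq of a closed polygon (signed by orientation).
polygon_moment <- function(poly, p, q) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  nxt <- c(seq_len(n)[-1], 1L)
  x2 <- poly[nxt, 1]; y2 <- poly[nxt, 2]
  J <- x1 * y2 - x2 * y1
  acc <- 0
  denom <- factorial(p + q + 2)
  for (a in 0:p) {
    for (b in 0:q) {
      coef <- choose(p, a) * choose(q, b) *
        factorial(a + b) * factorial(p + q - a - b) / denom
      acc <- acc + coef * sum(J * x1^a * x2^(p - a) * y1^b * y2^(q - b))
    }
  }
  acc
}

# All raw moments up to order 3 as a named list; orientation normalized so
# that m00 > 0.
polygon_moments <- function(poly) {
  orders <- list(
    c(0, 0), c(1, 0), c(0, 1), c(2, 0), c(1, 1), c(0, 2),
    c(3, 0), c(2, 1), c(1, 2), c(0, 3)
  )
  m <- lapply(orders, function(pq) polygon_moment(poly, pq[1], pq[2]))
  names(m) <- vapply(orders, function(pq) paste0("m", pq[1], pq[2]), "")
  if (m$m00 < 0) m <- lapply(m, function(v) -v)
  if (m$m00 == 0) abort("polygon_moments(): degenerate contour (zero area)")
  m
}

#' Hu moment invariants of a closed contour
#'
#' Computes the seven Hu invariants from exact polygon moments. They are
#' invariant to translation, scale and rotation of the contour, which makes
#' them suitable for matching a detected marker outline against its
#' registered reference outline regardless of marker distance or orientation.
#'
#' @param contour n x 2 matrix of (x, y) vertices of a closed polygon.
#' @return Numeric vector of length 7.
#' @export
hu_moments <- function(contour) {
  m <- polygon_moments(contour)
  xc <- m$m10 / m$m00
  yc <- m$m01 / m$m00
  # central moments
  mu20 <- m$m20 - xc * m$m10
  mu02 <- m$m02 - yc * m$m01
  mu11 <- m$m11 - xc * m$m01
  mu30 <- m$m30 - 3 * xc * m$m20 + 2 * xc^2 * m$m10
  mu03 <- m$m03 - 3 * yc * m$m02 + 2 * yc^2 * m$m01
  mu21 <- m$m21 - 2 * xc * m$m11 - yc * m$m20 + 2 * xc^2 * m$m01
  mu12 <- m$m12 - 2 * yc * m$m11 - xc * m$m02 + 2 * yc^2 * m$m10
  # scale-normalized
  n20 <- mu20 / m$m00^2
  n02 <- mu02 / m$m00^2
  n11 <- mu11 / m$m00^2
  n30 <- mu30 / m$m00^2.5
  n03 <- mu03 / m$m00^2.5
  n21 <- mu21 / m$m00^2.5
  n12 <- mu12 / m$m00^2.5
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

#' Hu-moment shape distance between two contours
#'
#' Log-scale Hu-invariant distance `sum_i |1/m_i^A - 1/m_i^B|` with
#' `m_i = sign(h_i) * log10(|h_i|)`; invariants with magnitude below `1e-30`
#' in either shape are skipped. Zero for identical contours and invariant
#' (up to numerical error) under translation, scaling and rotation of either
#' argument.
#'
#' @param contour_a,contour_b n x 2 contour matrices.
#' @return Non-negative shape distance.
#' @export
shape_distance <- function(contour_a, contour_b) {
  ha <- hu_moments(contour_a)
  hb <- hu_moments(contour_b)
  keep <- abs(ha) > 1e-30 & abs(hb) > 1e-30
  if (!any(keep)) return(0)
  ma <- sign(ha[keep]) * log10(abs(ha[keep]))
  mb <- sign(hb[keep]) * log10(abs(hb[keep]))
  # guard: log-moment exactly 0 would blow up 1/m; treat as skipped
  ok <- abs(ma) > 1e-12 & abs(mb) > 1e-12
  if (!any(ok)) return(0)
  sum(abs(1 / ma[ok] - 1 / mb[ok]))
}

#' Convert a shape distance to a similarity
#'
#' `sim_s = exp(-d_s)`: 1 for identical shapes, decaying towards 0 as the
#' Hu distance grows.
#'
#' @param d_s Non-negative shape distance.
#' @return Similarity in `(0, 1]`.
#' @export
shape_similarity <- function(d_s) {
  stopifnot(all(d_s >= 0))
  exp(-d_s)
}
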