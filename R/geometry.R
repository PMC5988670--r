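# Polygon primitives used by the contour-to-dots conversion. Polygons are
# n x 2 matrices; the closing edge is implicit.

#' Area centroid of a closed polygon
#'
#' Centroid of the uniform-density interior (not the vertex mean), computed by
#' the shoelace formula. This is the "centre of mass of the fish contour" used
#' throughout the decomposition.
#'
#' @param polygon numeric matrix (n x 2), vertices of a simple closed polygon.
#' @return numeric length-2 centroid (x, z).
#' @export
polygon_centroid <- function(polygon) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2L, nrow(polygon) >= 3L)
  x <- polygon[, 1]; z <- polygon[, 2]
  x2 <- c(x[-1], x[1]); z2 <- c(z[-1], z[1])
  cr <- x * z2 - x2 * z
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) stop("degenerate contour: polygon has zero area")
  c(sum((x + x2) * cr), sum((z + z2) * cr)) / (6 * a)
}

#' Perimeter of a closed polygon
#'
#' @param polygon numeric matrix (n x 2).
#' @return total edge length including the closing edge.
#' @export
polygon_perimeter <- function(polygon) {
  d <- polygon[c(2:nrow(polygon), 1), ] - polygon
  sum(sqrt(rowSums(d^2)))
}

# Points at arc-length positions `s` (measured from vertex 1, mm, wrapped
# modulo the perimeter) along the closed polyline.
contour_interpolate <- function(polygon, s) {
  n <- nrow(polygon)
  nxt <- polygon[c(2:n, 1), , drop = FALSE]
  el <- sqrt(rowSums((nxt - polygon)^2))
  cum <- c(0, cumsum(el))
  per <- cum[n + 1]
  if (per <= 0) stop("degenerate contour: zero perimeter")
  s <- s %% per
  i <- findInterval(s, cum, rightmost.closed = FALSE, all.inside = TRUE)
  frac <- ifelse(el[i] > 0, (s - cum[i]) / el[i], 0)
  polygon[i, , drop = FALSE] + frac * (nxt[i, , drop = FALSE] - polygon[i, , drop = FALSE])
}

# TRUE if no two non-adjacent edges of the closed polygon properly intersect.
polygon_is_simple <- function(polygon) {
  n <- nrow(polygon)
  p1 <- polygon
  p2 <- polygon[c(2:n, 1), , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1 & !(i == 1 & j == n)), arr.ind = TRUE)
  a <- p1[idx[, 1], , drop = FALSE]; b <- p2[idx[, 1], , drop = FALSE]
  c_ <- p1[idx[, 2], , drop = FALSE]; d <- p2[idx[, 2], , drop = FALSE]
  cross2 <- function(o, p, q) {
    (p[, 1] - o[, 1]) * (q[, 2] - o[, 2]) - (p[, 2] - o[, 2]) * (q[, 1] - o[, 1])
  }
  d1 <- cross2(a, b, c_); d2 <- cross2(a, b, d)
  d3 <- cross2(c_, d, a); d4 <- cross2(c_, d, b)
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}
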