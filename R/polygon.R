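# Low-level planar polygon geometry used by the outline generators, the
# landmarking protocol and the plate mesher. Polygons are n x 2 matrices of
# vertices, implicitly closed (vertex n connects back to vertex 1).

#' Signed area of a closed polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param xy n x 2 numeric matrix of vertices.
#' @return Signed area (numeric scalar).
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Perimeter of a closed polygon
#' @param xy n x 2 matrix of vertices.
#' @return Total boundary length.
#' @export
polygon_perimeter <- function(xy) {
  d <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE]) - xy
  sum(sqrt(rowSums(d^2)))
}

#' Area centroid of a closed polygon
#' @param xy n x 2 matrix of vertices.
#' @return Length-2 numeric vector.
#' @export
polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Maximum pairwise vertex distance (polygon diameter)
#'
#' Computed on the convex hull, so it equals the maximum caliper extent and is
#' invariant to rotation of the outline.
#'
#' @param xy n x 2 matrix of vertices.
#' @return Numeric scalar.
#' @export
polygon_diameter <- function(xy) {
  h <- xy[grDevices::chull(xy), , drop = FALSE]
  d2 <- as.matrix(stats::dist(h))
  max(d2)
}

# Orient a polygon counter-clockwise.
ensure_ccw <- function(xy) {
  if (polygon_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

# Do segments (p1,p2) and (p3,p4) properly intersect (or overlap)?
# Vectorised over rows of the four matrices.
segments_intersect <- function(p1, p2, p3, p4) {
  d1x <- p2[, 1] - p1[, 1]; d1y <- p2[, 2] - p1[, 2]
  d2x <- p4[, 1] - p3[, 1]; d2y <- p4[, 2] - p3[, 2]
  denom <- d1x * d2y - d1y * d2x
  ex <- p3[, 1] - p1[, 1]; ey <- p3[, 2] - p1[, 2]
  t <- (ex * d2y - ey * d2x) / denom
  u <- (ex * d1y - ey * d1x) / denom
  ok <- abs(denom) > .Machine$double.eps
  ok & t > 1e-12 & t < 1 - 1e-12 & u > 1e-12 & u < 1 - 1e-12
}

#' Simple-polygon check
#'
#' TRUE when no two non-adjacent boundary segments intersect.
#'
#' @param xy n x 2 matrix of vertices.
#' @return Logical scalar.
#' @export
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  a <- xy
  b <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  # skip adjacent segments (share an endpoint), incl. the wrap-around pair
  adj <- (j - i == 1) | (i == 1 & j == n)
  i <- i[!adj]; j <- j[!adj]
  if (!length(i)) return(TRUE)
  !any(segments_intersect(a[i, , drop = FALSE], b[i, , drop = FALSE],
                          a[j, , drop = FALSE], b[j, , drop = FALSE]))
}

#' Even-odd point-in-polygon test
#' @param pts m x 2 matrix of query points.
#' @param poly n x 2 polygon.
#' @return Logical vector of length m.
#' @export
point_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  px <- poly[, 1]; py <- poly[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  vapply(seq_len(nrow(pts)), function(k) {
    x <- pts[k, 1]; y <- pts[k, 2]
    crosses <- ((py > y) != (qy > y)) &
      (x < px + (y - py) * (qx - px) / (qy - py))
    sum(crosses) %% 2L == 1L
  }, logical(1))
}

# Intersections of the ray origin + t*dir (t > 0) with the polygon boundary.
# Returns a sorted vector of distances t (possibly empty).
ray_polygon_hits <- function(poly, origin = c(0, 0), theta) {
  dx <- cos(theta); dy <- sin(theta)
  ax <- poly[, 1] - origin[1]; ay <- poly[, 2] - origin[2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  ex <- bx - ax; ey <- by - ay
  denom <- dx * ey - dy * ex
  s <- (ax * ey - ay * ex) / denom     # distance along ray
  u <- (ax * dy - ay * dx) / denom     # position along segment
  keep <- abs(denom) > 1e-14 & u >= -1e-12 & u < 1 - 1e-12 & s > 1e-12
  sort(s[keep])
}

# Cumulative arc length of the closed boundary; entry i is the length from
# vertex 1 to vertex i along the path; total perimeter appended as attribute.
arc_lengths <- function(xy) {
  d <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE]) - xy
  seg <- sqrt(rowSums(d^2))
  s <- c(0, cumsum(seg)[-length(seg)])
  attr(s, "perimeter") <- sum(seg)
  attr(s, "seg") <- seg
  s
}

# Point on the closed boundary at arc-length position s (wrapped).
point_at_arclength <- function(xy, s) {
  al <- arc_lengths(xy)
  per <- attr(al, "perimeter")
  seg <- attr(al, "seg")
  s <- s %% per
  out <- matrix(0, length(s), 2)
  idx <- findInterval(s, al, rightmost.closed = FALSE)
  for (k in seq_along(s)) {
    i <- idx[k]
    j <- if (i == nrow(xy)) 1L else i + 1L
    t <- (s[k] - al[i]) / seg[i]
    out[k, ] <- xy[i, ] * (1 - t) + xy[j, ] * t
  }
  out
}

#' Resample a closed polygon by arc length
#' @param xy n x 2 polygon.
#' @param n number of output vertices.
#' @return n x 2 matrix, first point at the original first vertex.
#' @export
resample_polygon <- function(xy, n) {
  per <- polygon_perimeter(xy)
  point_at_arclength(xy, seq(0, per, length.out = n + 1)[-(n + 1)])
}
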