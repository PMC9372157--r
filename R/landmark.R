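# Standardized cross-hair landmarking: outlines are scaled/centred, then 8
# fixed landmarks are taken where the boundary crosses rays at 0, 45, ...,
# 315 degrees, and 7 semi-landmarks divide each inter-landmark boundary arc
# into 8 equal-length segments -> 64 ordered points per specimen.

#' Standardize an outline for landmarking
#'
#' Scales the outline so that the larger of its bounding-box width/height is
#' exactly 1000 units, and centres the bounding box on the origin (mimicking
#' manual centring of a digitised image). Idempotent.
#'
#' @param outline an [orbit_outline()].
#' @return The standardized outline; the applied scale (original units per
#'   standardized unit) is stored in attribute `"scale"`.
#' @export
standardize_outline <- function(outline) {
  v <- outline$vertices
  rng <- apply(v, 2, range)
  ext <- rng[2, ] - rng[1, ]
  if (max(ext) <= 0) stop("degenerate outline: zero bounding box")
  sc <- 1000 / max(ext)
  ctr <- (rng[1, ] + rng[2, ]) / 2
  out <- outline
  out$vertices <- sweep(v, 2, ctr) * sc
  attr(out, "scale") <- 1 / sc
  attr(out, "waist") <- attr(outline, "waist")
  out
}

#' Landmark configuration (8 fixed + 56 semi-landmarks)
#'
#' @param points 64 x 2 numeric matrix, ordered counter-clockwise starting at
#'   the 0-degree (anterior) fixed landmark.
#' @param specimen_id label.
#' @param scale original units per standardized unit.
#' @param covariates optional named list/data.frame row carried along.
#' @return Object of class `landmark_config`. Fixed landmarks sit at indices
#'   `seq(1, 64, by = 8)`.
#' @export
landmark_config <- function(points, specimen_id = "unnamed", scale = 1,
                            covariates = NULL) {
  points <- as.matrix(points)
  if (nrow(points) != 64 || ncol(points) != 2)
    stop("a landmark configuration has exactly 64 2-D points")
  structure(list(points = points, fixed_idx = seq(1L, 64L, by = 8L),
                 specimen_id = specimen_id, scale = scale,
                 covariates = covariates),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("landmark configuration '%s': 64 points (8 fixed), scale %.4g\n",
              x$specimen_id, x$scale))
  invisible(x)
}

#' Place the 64-point cross-hair landmark configuration
#'
#' The outline must be standardized ([standardize_outline()]). Fixed landmark
#' k (k = 0..7) is the intersection of the boundary with the ray from the
#' origin at angle 45k degrees; where a ray crosses the boundary more than
#' once (deeply constricted outlines) the intersection farthest from the
#' origin is used, keeping landmarks on the outer margin. Seven
#' semi-landmarks split each boundary arc between consecutive fixed landmarks
#' into eight equal arc-length segments.
#'
#' @param outline a standardized [orbit_outline()].
#' @param specimen_id label; defaults to the outline's taxon.
#' @return A [landmark_config()].
#' @export
place_landmarks <- function(outline, specimen_id = outline$taxon) {
  v <- outline$vertices
  rng <- apply(v, 2, range)
  if (abs(max(rng[2, ] - rng[1, ]) - 1000) > 1e-3)
    stop("outline is not standardized; call standardize_outline() first")
  al <- arc_lengths(v)
  per <- attr(al, "perimeter")
  angs <- (0:7) * pi / 4
  s_fix <- numeric(8)
  for (k in 1:8) {
    hits <- ray_polygon_hits(v, c(0, 0), angs[k])
    if (!length(hits))
      stop("no boundary intersection on the ray at ",
           (k - 1) * 45, " degrees")
    t_far <- hits[length(hits)]
    p <- t_far * c(cos(angs[k]), sin(angs[k]))
    s_fix[k] <- arclength_of_point(v, al, p)
  }
  # the 8 stations must appear in counter-clockwise (increasing s) cyclic
  # order, otherwise the outline defeats the outer-margin fallback
  s_rel <- (s_fix - s_fix[1]) %% per
  if (any(diff(s_rel) <= 0)) {
    bad <- which(diff(s_rel) <= 0)[1] * 45
    stop("outline is too far from star-shaped: landmark order breaks at ",
         "the ray at ", bad, " degrees")
  }
  pts <- matrix(0, 64, 2)
  for (k in 1:8) {
    s0 <- s_fix[k]
    s1 <- if (k < 8) s_fix[k + 1] else s_fix[1] + per
    arc <- (s1 - s0) %% per
    if (arc == 0) arc <- per
    ss <- s0 + arc * (0:7) / 8
    pts[(k - 1) * 8 + (1:8), ] <- point_at_arclength(v, ss)
  }
  landmark_config(pts, specimen_id = specimen_id,
                  scale = attr(outline, "scale") %||% 1,
                  covariates = list(taxon = outline$taxon,
                                    group = outline$group,
                                    diet = outline$diet,
                                    skull_length_mm = outline$skull_length,
                                    time_bin = outline$time_bin,
                                    waist = attr(outline, "waist")))
}

# Arc-length position of a point lying on the polygon boundary.
arclength_of_point <- function(v, al, p) {
  n <- nrow(v)
  a <- v
  b <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  e <- b - a
  len2 <- rowSums(e^2)
  t <- ((p[1] - a[, 1]) * e[, 1] + (p[2] - a[, 2]) * e[, 2]) / len2
  t <- pmin(pmax(t, 0), 1)
  qx <- a[, 1] + t * e[, 1]; qy <- a[, 2] + t * e[, 2]
  d2 <- (qx - p[1])^2 + (qy - p[2])^2
  i <- which.min(d2)
  al[i] + t[i] * sqrt(len2[i])
}

#' Landmark a list of outlines
#'
#' Convenience wrapper: standardizes then landmarks every outline.
#'
#' @param outlines list of [orbit_outline()]s.
#' @return List of [landmark_config()]s.
#' @export
landmark_outlines <- function(outlines) {
  lapply(outlines, function(o) place_landmarks(standardize_outline(o)))
}
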