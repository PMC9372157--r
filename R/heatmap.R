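# Thin-plate-spline interpolation of scalar fields (skull length, diet
# score, SCF) over 2-D morphospace scores, masked away from the data so the
# surface never extrapolates into empty morphospace.

tps_kernel <- function(r2) {
  out <- r2
  out[] <- 0
  pos <- r2 > 0
  out[pos] <- 0.5 * r2[pos] * log(r2[pos])  # r^2 log r = 0.5 r^2 log r^2
  out
}

#' Thin-plate-spline surface over morphospace scores
#'
#' Exact (zero-smoothing) thin-plate-spline interpolation of per-specimen
#' scalars over their (PC1, PC2) scores, evaluated on a regular grid
#' spanning the score range with a 5% margin. Grid cells farther than
#' `mask_frac` of the score-range diagonal from every datum are masked
#' (`NA`), so the heatmap does not extrapolate.
#'
#' @param scores n x 2 matrix of (PC1, PC2) scores.
#' @param values length-n numeric vector of finite values.
#' @param resolution grid size per axis.
#' @param mask_frac masking cutoff as a fraction of the score-range
#'   diagonal.
#' @return A `heatmap_surface`: `grid_x`, `grid_y`, `values`
#'   (resolution x resolution matrix, `NA` where masked), `mask` (logical),
#'   plus the fitted spline for reuse via [predict_surface()].
#' @export
interpolate_surface <- function(scores, values, resolution = 100,
                                mask_frac = 0.1) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  values <- as.numeric(values)
  n <- nrow(scores)
  if (n < 4) stop("need at least 4 score points")
  if (any(!is.finite(values))) stop("values must be finite")
  dup <- duplicated(round(scores, 12))
  if (any(dup)) {
    keep <- !dup
    scores <- scores[keep, , drop = FALSE]
    values <- values[keep]
    n <- nrow(scores)
  }
  if (qr(cbind(1, scores))$rank < 3)
    stop("score points are collinear; a thin-plate spline is undefined")
  d2 <- as.matrix(stats::dist(scores))^2
  K <- tps_kernel(d2)
  P <- cbind(1, scores)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  coef <- solve(A, c(values, 0, 0, 0))
  spline <- list(centers = scores, w = coef[seq_len(n)],
                 a = coef[n + 1:3])
  rng <- apply(scores, 2, range)
  pad <- 0.05 * (rng[2, ] - rng[1, ])
  gx <- seq(rng[1, 1] - pad[1], rng[2, 1] + pad[1], length.out = resolution)
  gy <- seq(rng[1, 2] - pad[2], rng[2, 2] + pad[2], length.out = resolution)
  pts <- cbind(rep(gx, times = resolution), rep(gy, each = resolution))
  z <- eval_tps(spline, pts)
  cutoff <- mask_frac * sqrt(sum((rng[2, ] - rng[1, ])^2))
  nearest <- apply(pts, 1, function(p)
    min((scores[, 1] - p[1])^2 + (scores[, 2] - p[2])^2))
  mask <- sqrt(nearest) > cutoff
  z[mask] <- NA_real_
  structure(list(grid_x = gx, grid_y = gy,
                 values = matrix(z, resolution, resolution),
                 mask = matrix(mask, resolution, resolution),
                 spline = spline, cutoff = cutoff),
            class = "heatmap_surface")
}

eval_tps <- function(spline, pts) {
  ctr <- spline$centers
  z <- spline$a[1] + pts %*% spline$a[2:3]
  for (i in seq_len(nrow(ctr))) {
    r2 <- (pts[, 1] - ctr[i, 1])^2 + (pts[, 2] - ctr[i, 2])^2
    z <- z + spline$w[i] * tps_kernel(r2)
  }
  drop(z)
}

#' Evaluate a fitted heatmap surface at arbitrary score points
#' @param surface a [interpolate_surface()] result.
#' @param pts m x 2 matrix of (PC1, PC2) points.
#' @return Numeric vector (no masking applied).
#' @export
predict_surface <- function(surface, pts) {
  eval_tps(surface$spline, as.matrix(pts))
}

#' Ordinal encoding of dietary regimes
#'
#' herbivore = 0, omnivore = 0.5, carnivore = 1.
#'
#' @param diet character vector of diet labels.
#' @return Numeric vector.
#' @export
diet_encoding <- function(diet) {
  code <- c(herbivore = 0, omnivore = 0.5, carnivore = 1)
  bad <- setdiff(unique(diet), names(code))
  if (length(bad)) stop("unknown diet label(s): ", paste(bad, collapse = ", "))
  unname(code[diet])
}

#' Export a heatmap surface as a CSV grid
#' @param surface a `heatmap_surface`.
#' @param path output path (long format: x, y, value).
#' @return The path, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  df <- data.frame(
    x = rep(surface$grid_x, times = length(surface$grid_y)),
    y = rep(surface$grid_y, each = length(surface$grid_x)),
    value = as.vector(surface$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
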