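# Generalized Procrustes analysis: iterative removal of translation, scale
# (optional) and rotation across a sample of landmark configurations,
# yielding shape coordinates around a consensus. Works in any dimension
# (2-D outlines here; 3-D landmark sets in the deformation module).

centroid_size <- function(x) sqrt(sum(sweep(x, 2, colMeans(x))^2))

# Optimal rotation R (proper, via Kabsch/SVD) minimising ||X R - Y||_F.
kabsch_rotation <- function(x, y) {
  h <- crossprod(x, y)
  s <- svd(h)
  d <- sign(det(s$u) * det(s$v))
  corr <- diag(rep(1, ncol(x))); corr[ncol(x), ncol(x)] <- d
  s$u %*% corr %*% t(s$v)
}

as_config_list <- function(configs) {
  lapply(configs, function(cf) {
    m <- if (inherits(cf, "landmark_config")) cf$points else as.matrix(cf)
    storage.mode(m) <- "double"
    m
  })
}

config_ids <- function(configs) {
  ids <- vapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    if (inherits(cf, "landmark_config")) cf$specimen_id
    else names(configs)[i] %||% paste0("spec", i)
  }, character(1))
  ids[!nzchar(ids)] <- paste0("spec", which(!nzchar(ids)))
  make.unique(ids)
}

#' Generalized Procrustes superimposition
#'
#' Centres every configuration, optionally scales it to unit centroid size,
#' and iteratively rotates all configurations onto their consensus until the
#' consensus stabilises.
#'
#' @param configs list of [landmark_config()]s or k x d matrices (equal k, d).
#' @param tol convergence threshold on the Frobenius change of the consensus.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param scale scale configurations to unit centroid size (standard GPA).
#'   With `scale = FALSE` only translation and rotation are removed, so size
#'   change remains part of the signal.
#' @return Object of class `orbit_gpa`: `aligned` (k x d x n array),
#'   `centroid_sizes`, `consensus`, `iterations`, `converged`, `ids`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100, scale = TRUE) {
  mats <- as_config_list(configs)
  n <- length(mats)
  if (n < 2) stop("GPA needs at least 2 configurations")
  k <- nrow(mats[[1]]); d <- ncol(mats[[1]])
  if (!all(vapply(mats, function(m) nrow(m) == k && ncol(m) == d,
                  logical(1))))
    stop("all configurations must share landmark count and dimension")
  cs <- vapply(mats, centroid_size, numeric(1))
  if (any(cs < .Machine$double.eps))
    stop("degenerate configuration with zero centroid size")
  x <- array(0, c(k, d, n))
  for (i in seq_len(n)) {
    m <- sweep(mats[[i]], 2, colMeans(mats[[i]]))
    x[, , i] <- if (scale) m / cs[i] else m
  }
  consensus <- x[, , 1]
  if (scale) consensus <- consensus / centroid_size(consensus)
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    for (i in seq_len(n)) x[, , i] <- x[, , i] %*%
        kabsch_rotation(x[, , i], consensus)
    new_consensus <- apply(x, c(1, 2), mean)
    if (scale) new_consensus <- new_consensus / centroid_size(new_consensus)
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  # final pass so every configuration is aligned to the final consensus
  for (i in seq_len(n)) x[, , i] <- x[, , i] %*%
      kabsch_rotation(x[, , i], consensus)
  structure(list(aligned = x, centroid_sizes = cs,
                 consensus = apply(x, c(1, 2), mean),
                 iterations = iterations, converged = converged,
                 scaled = scale, ids = config_ids(configs)),
            class = "orbit_gpa")
}

#' @export
print.orbit_gpa <- function(x, ...) {
  cat(sprintf(
    "GPA of %d configurations (%d landmarks, %d-D): %d iterations%s\n",
    dim(x$aligned)[3], dim(x$aligned)[1], dim(x$aligned)[2], x$iterations,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Root-summed-squared difference after centring, optional unit-size scaling,
#' and optimal rotation of `x` onto `y`.
#'
#' @param x,y k x d matrices or [landmark_config()]s.
#' @param scale remove size before comparing.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(x, y, scale = TRUE) {
  m <- as_config_list(list(x, y))
  a <- sweep(m[[1]], 2, colMeans(m[[1]]))
  b <- sweep(m[[2]], 2, colMeans(m[[2]]))
  if (scale) { a <- a / centroid_size(a); b <- b / centroid_size(b) }
  a <- a %*% kabsch_rotation(a, b)
  sqrt(sum((a - b)^2))
}
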