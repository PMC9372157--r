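# Principal component morphospace over Procrustes-aligned coordinates, the
# PC1-3 Euclidean "non-circularity" distance, and projection of new
# configurations into a fitted space.

flatten_configs <- function(aligned) {
  n <- dim(aligned)[3]
  t(vapply(seq_len(n), function(i) as.vector(aligned[, , i]),
           numeric(dim(aligned)[1] * dim(aligned)[2])))
}

#' Principal component analysis of a Procrustes superimposition
#'
#' Covariance PCA of the aligned coordinates (the standard choice for
#' Procrustes shape data). Eigenvector signs are fixed deterministically: the
#' largest-magnitude loading of every PC is made positive, so repeated runs
#' and permuted inputs give bitwise-identical axes.
#'
#' @param res an [gpa()] result.
#' @return Object of class `morphospace`: `eigenvectors` (p x r, orthonormal
#'   columns), `variance_fraction` (non-increasing, summing to 1 over nonzero
#'   PCs), `scores` (n x r, zero column means), `center` (column means of the
#'   flattened aligned coordinates), `consensus`, `n_effective` (rank),
#'   `ids`, and the landmark count/dimension needed for projection.
#' @export
morphospace_pca <- function(res) {
  stopifnot(inherits(res, "orbit_gpa"))
  x <- flatten_configs(res$aligned)
  n <- nrow(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc)
  ev <- sv$d^2 / (n - 1)
  total <- sum(ev)
  r <- min(n - 1, ncol(x))
  vecs <- sv$v[, seq_len(r), drop = FALSE]
  scores <- xc %*% vecs
  if (total < 1e-24) {
    vf <- rep(0, r)
    scores[] <- 0
    n_eff <- 0L
  } else {
    vf <- ev[seq_len(r)] / total
    n_eff <- sum(ev[seq_len(r)] > max(ev) * 1e-12)
  }
  # deterministic sign convention
  for (j in seq_len(r)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) {
      vecs[, j] <- -vecs[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(r))
  structure(list(eigenvectors = vecs, variance_fraction = vf,
                 scores = scores, center = ctr, consensus = res$consensus,
                 n_effective = n_eff, ids = res$ids,
                 k = dim(res$aligned)[1], d = dim(res$aligned)[2],
                 scaled = res$scaled),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("morphospace: %d specimens, rank %d\n",
              nrow(x$scores), x$n_effective))
  shown <- seq_len(min(3, length(x$variance_fraction)))
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", shown, 100 * x$variance_fraction[shown]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Euclidean shape distance over PC1-3
#'
#' The morphospace origin represents the consensus (near-circular) orbit;
#' the distance of each specimen from the origin over the first three PCs
#' quantifies its deviation from circularity. Missing PCs (rank < 3) count
#' as zero.
#'
#' @param model a [morphospace_pca()] result, or a score matrix.
#' @return data.frame with `specimen_id` and `d_pc123`.
#' @export
pc_distance <- function(model) {
  sc <- if (inherits(model, "morphospace")) model$scores else as.matrix(model)
  ids <- if (inherits(model, "morphospace")) model$ids
         else rownames(sc) %||% paste0("spec", seq_len(nrow(sc)))
  s3 <- matrix(0, nrow(sc), 3)
  take <- seq_len(min(3, ncol(sc)))
  s3[, take] <- sc[, take, drop = FALSE]
  data.frame(specimen_id = ids, d_pc123 = sqrt(rowSums(s3^2)),
             stringsAsFactors = FALSE)
}

#' Project a new configuration into a fitted morphospace
#'
#' Ordinary Procrustes fit of the configuration onto the consensus (centre,
#' unit-centroid-size scaling if the GPA was scaled, optimal rotation),
#' then projection onto the eigenbasis. A training configuration projects
#' onto its stored scores.
#'
#' @param model a [morphospace_pca()] result.
#' @param new_config [landmark_config()] or k x d matrix using the same
#'   landmarking protocol.
#' @return Numeric vector of PC scores.
#' @export
project_config <- function(model, new_config) {
  m <- as_config_list(list(new_config))[[1]]
  if (nrow(m) != model$k || ncol(m) != model$d)
    stop("landmark count mismatch: model uses ", model$k, " x ", model$d,
         ", got ", nrow(m), " x ", ncol(m))
  m <- sweep(m, 2, colMeans(m))
  if (model$scaled) m <- m / centroid_size(m)
  m <- m %*% kabsch_rotation(m, model$consensus)
  drop(as.vector(m) %*% model$eigenvectors -
         model$center %*% model$eigenvectors)
}

#' Morphospace of an empirical TPS landmark sample
#'
#' Runs the full GPA + covariance-PCA pipeline on digitised landmark files,
#' e.g. the deposited 64-point orbit configurations of a fossil sample.
#'
#' @param tps_paths character vector of TPS file paths (or a directory, in
#'   which case all `*.tps`/`*.TPS` files inside are read).
#' @return A [morphospace_pca()] result.
#' @export
empirical_morphospace <- function(tps_paths) {
  if (length(tps_paths) == 1 && dir.exists(tps_paths))
    tps_paths <- list.files(tps_paths, pattern = "\\.tps$", full.names = TRUE,
                            ignore.case = TRUE)
  if (!length(tps_paths)) stop("no TPS files found")
  configs <- unlist(lapply(tps_paths, read_tps), recursive = FALSE)
  morphospace_pca(gpa(configs))
}

#' Export morphospace scores and shape distances as CSV
#'
#' @param model a [morphospace_pca()] result.
#' @param path output CSV path.
#' @param covariates optional data.frame (one row per specimen, same order).
#' @param n_pc number of PC columns to write.
#' @return The path, invisibly.
#' @export
write_scores_csv <- function(model, path, covariates = NULL, n_pc = 5) {
  n_pc <- min(n_pc, ncol(model$scores))
  df <- data.frame(specimen_id = model$ids,
                   model$scores[, seq_len(n_pc), drop = FALSE],
                   d_pc123 = pc_distance(model)$d_pc123,
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
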