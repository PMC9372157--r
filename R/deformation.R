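# Deformation-space quantification: undeformed/deformed landmark pairs are
# jointly superimposed (Procrustes), jointly decomposed by PCA, and the
# Euclidean distance between the members of each pair over the first three
# PCs measures how strongly the model deforms.

#' Undeformed/deformed landmark pair
#'
#' @param model_id label.
#' @param undeformed,deformed k x d matrices (d = 2 or 3) with matching
#'   landmark schemes.
#' @return A `deformation_pair` list.
#' @export
deformation_pair <- function(model_id, undeformed, deformed) {
  u <- as.matrix(undeformed); v <- as.matrix(deformed)
  if (!all(dim(u) == dim(v)))
    stop("undeformed and deformed configurations must match in landmark ",
         "count and dimensionality")
  structure(list(model_id = model_id, undeformed = u, deformed = v,
                 d_euclid = NA_real_),
            class = "deformation_pair")
}

#' Deformation distances for a set of model pairs
#'
#' All configurations (undeformed and deformed, two per pair) enter a joint
#' Procrustes superimposition and a joint PCA; each pair's `d_euclid` is the
#' Euclidean distance between its two configurations over PC1-3.
#'
#' By default the Procrustes step does not rescale to unit centroid size
#' (`use_scaling = FALSE`): uniform size change is part of the deformation
#' signal. Set `use_scaling = TRUE` to reproduce a standard
#' (scale-removing) superimposition.
#'
#' @param pairs list of [deformation_pair()]s (>= 2).
#' @param use_scaling remove size in the superimposition.
#' @return List: `pairs` (with `d_euclid` filled), `model`
#'   (the joint [morphospace_pca()]), `distances` (data.frame model_id,
#'   d_euclid).
#' @export
deformation_distances <- function(pairs, use_scaling = FALSE) {
  stopifnot(length(pairs) >= 2)
  ks <- vapply(pairs, function(p) nrow(p$undeformed), numeric(1))
  ds <- vapply(pairs, function(p) ncol(p$undeformed), numeric(1))
  if (length(unique(ks)) != 1 || length(unique(ds)) != 1)
    stop("all pairs must share one landmark scheme (mixed landmark counts)")
  configs <- list()
  for (p in pairs) {
    configs[[paste0(p$model_id, ".undeformed")]] <- p$undeformed
    configs[[paste0(p$model_id, ".deformed")]] <- p$deformed
  }
  g <- gpa(configs, scale = use_scaling)
  model <- morphospace_pca(g)
  sc <- model$scores
  s3 <- matrix(0, nrow(sc), 3)
  take <- seq_len(min(3, ncol(sc)))
  s3[, take] <- sc[, take, drop = FALSE]
  n <- length(pairs)
  d <- sqrt(rowSums((s3[2 * seq_len(n) - 1, , drop = FALSE] -
                     s3[2 * seq_len(n), , drop = FALSE])^2))
  for (i in seq_len(n)) pairs[[i]]$d_euclid <- d[i]
  list(pairs = pairs, model = model,
       distances = data.frame(
         model_id = vapply(pairs, function(p) p$model_id, character(1)),
         d_euclid = d, stringsAsFactors = FALSE))
}

#' Landmark a solved plate model before and after deformation
#'
#' Samples landmarks at fixed parametric stations: a quarter of them spread
#' along the outer plate boundary and the rest equally spaced around the
#' hole margin (all snapped to the nearest mesh node). Deformed positions
#' add the nodal displacement.
#'
#' @param result a `fea_result`.
#' @param mesh the solved `orbit_mesh`.
#' @param model_id label.
#' @param n_landmarks total landmark count.
#' @return A [deformation_pair()].
#' @export
sample_fea_landmarks <- function(result, mesh, model_id = "model",
                                 n_landmarks = 32) {
  if (n_landmarks > nrow(mesh$nodes))
    stop("n_landmarks exceeds the mesh node count")
  n_outer <- max(8L, round(n_landmarks / 4))
  n_hole <- n_landmarks - n_outer
  outer_idx <- unique(unlist(mesh$boundary[c("bottom", "right", "top",
                                             "left")]))
  ctr <- colMeans(apply(mesh$nodes, 2, range))
  pick_by_angle <- function(idx, m) {
    if (!length(idx)) return(integer(0))
    ang <- atan2(mesh$nodes[idx, 2] - ctr[2],
                 mesh$nodes[idx, 1] - ctr[1]) %% (2 * pi)
    stations <- (seq_len(m) - 1) * 2 * pi / m
    vapply(stations, function(a) {
      dd <- pmin(abs(ang - a), 2 * pi - abs(ang - a))
      idx[which.min(dd)]
    }, integer(1))
  }
  sel <- unique(c(pick_by_angle(outer_idx, n_outer),
                  pick_by_angle(mesh$boundary$hole_margin, n_hole)))
  und <- mesh$nodes[sel, , drop = FALSE]
  def <- und + result$displacements[sel, , drop = FALSE]
  deformation_pair(model_id, und, def)
}
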