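# Linear-elastic plane-stress finite elements: 3-node constant-strain
# triangles, sparse assembly, point and consistent edge-traction loads,
# nodal stress recovery by area-weighted averaging. Units: mm, N, MPa.

#' Isotropic plane-stress material
#'
#' Default is alligator-bone-like cortical bone used as a proxy for
#' archosauromorph bone: E = 15.00 GPa (15000 MPa), Poisson ratio 0.29.
#'
#' @param youngs_modulus Young's modulus in MPa.
#' @param poisson_ratio Poisson ratio, in (-1, 0.5).
#' @return A `fe_material` list.
#' @export
fe_material <- function(youngs_modulus = 15000, poisson_ratio = 0.29) {
  if (youngs_modulus <= 0) stop("youngs_modulus must be > 0")
  if (poisson_ratio <= -1 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in (-1, 0.5)")
  structure(list(E = youngs_modulus, nu = poisson_ratio),
            class = "fe_material")
}

#' Plate-with-hole geometry
#'
#' Places an orbit outline at the centre of a square plate, scaled so the
#' outline's maximum dimension is `hole_fraction` of the plate width. Plate
#' proportions are fixed at height:width:thickness = 10:10:1.
#'
#' @param hole an [orbit_outline()], or `NULL` for an unpierced plate.
#' @param hole_fraction hole maximum dimension as a fraction of plate width.
#' @param plate_w plate width (mm).
#' @return A `plate_geom` list: `plate_w`, `plate_h`, `thickness`, `hole`
#'   (repositioned outline or `NULL`), `hole_fraction`.
#' @export
build_plate <- function(hole, hole_fraction = 0.4, plate_w = 10) {
  W <- plate_w
  geom <- list(plate_w = W, plate_h = W, thickness = W / 10,
               hole = NULL, hole_fraction = hole_fraction)
  if (!is.null(hole)) {
    v <- hole$vertices
    v <- sweep(v, 2, polygon_centroid(v))
    v <- v * (hole_fraction * W / polygon_diameter(v))
    v <- sweep(v, 2, c(W / 2, W / 2), `+`)
    margin <- c(min(v[, 1]), W - max(v[, 1]), min(v[, 2]), W - max(v[, 2]))
    if (any(margin < 0.05 * W))
      stop("hole_fraction = ", hole_fraction, " leaves less than 5% ",
           "clearance between hole and plate edge")
    hole$vertices <- v
    geom$hole <- hole
  }
  structure(geom, class = "plate_geom")
}

#' Plan area of the load-bearing plate material
#' @param geom a [build_plate()] geometry.
#' @return Plate area minus hole area.
#' @export
bearing_area <- function(geom) {
  a <- geom$plate_w * geom$plate_h
  if (!is.null(geom$hole)) a <- a - abs(polygon_area(geom$hole$vertices))
  a
}

#' Quasi-homothetic load scaling
#'
#' Scales the per-load force of a new model from a reference model so the
#' force-to-load-bearing-area ratio is constant across differently pierced
#' plates, keeping their stress fields comparable.
#'
#' @param ref_geom,new_geom [build_plate()] geometries (same plate size).
#' @param ref_force per-load force of the reference model (N).
#' @return Per-load force for the new model (N).
#' @export
scale_loads <- function(ref_geom, new_geom, ref_force = 1) {
  a_ref <- bearing_area(ref_geom) * ref_geom$thickness
  a_new <- bearing_area(new_geom) * new_geom$thickness
  if (a_ref <= .Machine$double.eps) stop("zero reference bearing area")
  ref_force * a_new / a_ref
}

stations_on <- function(mesh, side, W, H) {
  idx <- mesh$boundary[[side]]
  if (!length(idx)) stop("mesh has no '", side, "' boundary nodes")
  along <- if (side %in% c("top", "bottom")) 1L else 2L
  ext <- if (along == 1L) W else H
  coords <- mesh$nodes[idx, along]
  vapply(c(0.25, 0.5, 0.75) * ext, function(s) idx[which.min(abs(coords - s))],
         integer(1))
}

SCENARIOS <- c("dv_compression", "anterior_shear", "ap_compression",
               "dorsal_shear")

#' Boundary conditions for the four functional scenarios
#'
#' Axis convention: x runs anteroposteriorly (posterior = +x), y runs
#' dorsoventrally (dorsal = +y). Each scenario fully fixes three equidistant
#' nodes (at 1/4, 1/2, 3/4 of the constrained margin) and applies three
#' equal point loads at the same stations of the loaded margin:
#' \describe{
#'   \item{dv_compression}{ventral margin fixed; ventrally-directed loads on
#'     the dorsal margin.}
#'   \item{anterior_shear}{ventral margin fixed; posteriorly-directed loads
#'     on the dorsal margin.}
#'   \item{ap_compression}{posterior margin fixed; posteriorly-directed
#'     loads on the anterior margin.}
#'   \item{dorsal_shear}{posterior margin fixed; ventrally-directed loads on
#'     the anterior margin.}
#' }
#'
#' @param mesh an `orbit_mesh`.
#' @param scenario one of `r paste0('"', SCENARIOS, '"', collapse = ", ")`.
#' @param force_per_load magnitude of each of the three loads (N).
#' @param W,H plate extent (defaults: bounding box of the mesh).
#' @return A `load_case` list: `scenario`, `fixed` (node indices, both dofs),
#'   `forces` (n x 2 matrix), `force_per_load`.
#' @export
make_load_case <- function(mesh, scenario, force_per_load = 1,
                           W = max(mesh$nodes[, 1]),
                           H = max(mesh$nodes[, 2])) {
  scenario <- match.arg(scenario, SCENARIOS)
  sides <- switch(scenario,
    dv_compression = list(fix = "bottom", load = "top", dir = c(0, -1)),
    anterior_shear = list(fix = "bottom", load = "top", dir = c(1, 0)),
    ap_compression = list(fix = "right", load = "left", dir = c(1, 0)),
    dorsal_shear = list(fix = "right", load = "left", dir = c(0, -1)))
  fixed <- stations_on(mesh, sides$fix, W, H)
  loaded <- stations_on(mesh, sides$load, W, H)
  forces <- matrix(0, nrow(mesh$nodes), 2)
  for (nd in loaded) forces[nd, ] <- forces[nd, ] + force_per_load * sides$dir
  structure(list(scenario = scenario, fixed = fixed, fixed_dofs = "both",
                 forces = forces, force_per_load = force_per_load),
            class = "load_case")
}

# consecutive boundary node pairs along one side, sorted by position
side_segments <- function(mesh, side) {
  idx <- mesh$boundary[[side]]
  along <- if (side %in% c("top", "bottom")) 1L else 2L
  idx <- idx[order(mesh$nodes[idx, along])]
  cbind(idx[-length(idx)], idx[-1])
}

#' Uniform edge-traction benchmark load case
#'
#' Applies a uniform normal traction (consistent nodal forces) on one plate
#' edge and roller supports on the opposite edge, producing a uniform
#' uniaxial stress state in an unpierced plate — the far-field configuration
#' of the classic hole-in-plate stress concentration benchmarks.
#'
#' @param mesh an `orbit_mesh`.
#' @param edge loaded edge (`"top"` or `"left"`).
#' @param q traction magnitude (MPa), applied towards the plate (compression).
#' @param thickness plate thickness (mm).
#' @return A `load_case` with per-dof constraints (`fixed_x`, `fixed_y`).
#' @export
make_traction_case <- function(mesh, edge = c("top", "left"), q = 1,
                               thickness = 1) {
  edge <- match.arg(edge)
  seg <- side_segments(mesh, edge)
  len <- sqrt(rowSums((mesh$nodes[seg[, 1], , drop = FALSE] -
                       mesh$nodes[seg[, 2], , drop = FALSE])^2))
  forces <- matrix(0, nrow(mesh$nodes), 2)
  dir <- if (edge == "top") c(0, -1) else c(1, 0)
  for (s in seq_len(nrow(seg))) {
    f <- q * thickness * len[s] / 2
    forces[seg[s, 1], ] <- forces[seg[s, 1], ] + f * dir
    forces[seg[s, 2], ] <- forces[seg[s, 2], ] + f * dir
  }
  if (edge == "top") {
    fixed_y <- mesh$boundary$bottom
    mid <- fixed_y[which.min(abs(mesh$nodes[fixed_y, 1] -
                                   stats::median(mesh$nodes[, 1])))]
    fixed_x <- mid
    scen <- "traction_y"
  } else {
    fixed_x <- mesh$boundary$right
    mid <- fixed_x[which.min(abs(mesh$nodes[fixed_x, 2] -
                                   stats::median(mesh$nodes[, 2])))]
    fixed_y <- mid
    scen <- "traction_x"
  }
  structure(list(scenario = scen, fixed = NULL, fixed_dofs = "split",
                 fixed_x = fixed_x, fixed_y = fixed_y,
                 forces = forces, force_per_load = q),
            class = "load_case")
}

plane_stress_D <- function(mat) {
  f <- mat$E / (1 - mat$nu^2)
  matrix(c(f, f * mat$nu, 0,
           f * mat$nu, f, 0,
           0, 0, f * (1 - mat$nu) / 2), 3, 3)
}

#' Assemble the global plane-stress stiffness matrix
#' @param mesh an `orbit_mesh`.
#' @param material a [fe_material()].
#' @param thickness plate thickness (mm).
#' @return Sparse symmetric `2n x 2n` stiffness matrix.
#' @export
assemble_stiffness <- function(mesh, material, thickness) {
  nd <- mesh$nodes; el <- mesh$elements
  D <- plane_stress_D(material)
  x <- matrix(nd[el, 1], ncol = 3); y <- matrix(nd[el, 2], ncol = 3)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  c_ <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  A <- 0.5 * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  w <- thickness / (4 * A)
  d11 <- D[1, 1]; d12 <- D[1, 2]; d33 <- D[3, 3]
  ne <- nrow(el)
  ii <- jj <- vv <- vector("list", 36)
  s <- 0L
  for (i in 1:3) for (j in 1:3) {
    kxx <- w * (d11 * b[, i] * b[, j] + d33 * c_[, i] * c_[, j])
    kxy <- w * (d12 * b[, i] * c_[, j] + d33 * c_[, i] * b[, j])
    kyx <- w * (d12 * c_[, i] * b[, j] + d33 * b[, i] * c_[, j])
    kyy <- w * (d11 * c_[, i] * c_[, j] + d33 * b[, i] * b[, j])
    gi <- el[, i]; gj <- el[, j]
    ii[[s + 1L]] <- 2L * gi - 1L; jj[[s + 1L]] <- 2L * gj - 1L
    vv[[s + 1L]] <- kxx
    ii[[s + 2L]] <- 2L * gi - 1L; jj[[s + 2L]] <- 2L * gj
    vv[[s + 2L]] <- kxy
    ii[[s + 3L]] <- 2L * gi; jj[[s + 3L]] <- 2L * gj - 1L
    vv[[s + 3L]] <- kyx
    ii[[s + 4L]] <- 2L * gi; jj[[s + 4L]] <- 2L * gj
    vv[[s + 4L]] <- kyy
    s <- s + 4L
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(2L, 2L) * nrow(nd))
}

fixed_dof_indices <- function(lc, n) {
  if (identical(lc$fixed_dofs, "split")) {
    c(2L * lc$fixed_x - 1L, 2L * lc$fixed_y)
  } else {
    as.vector(rbind(2L * lc$fixed - 1L, 2L * lc$fixed))
  }
}

#' Solve a plate problem
#'
#' Direct sparse solve of the constrained linear system, followed by stress
#' recovery: constant element stresses, area-weighted nodal averaging of the
#' stress components, and nodal von Mises intensity
#' `sqrt(sxx^2 - sxx*syy + syy^2 + 3*txy^2)`.
#'
#' @param mesh an `orbit_mesh`.
#' @param material a [fe_material()].
#' @param loadcase a [make_load_case()] / [make_traction_case()] case, or a
#'   list with `forces` and displacement constraints.
#' @param thickness plate thickness (mm).
#' @param prescribed optional named numeric vector of prescribed dof values
#'   (names = dof index), overriding the load case constraints (used for
#'   patch tests).
#' @return A `fea_result`: `displacements` (n x 2), `element_stress`
#'   (ne x 3: sxx, syy, txy), `nodal_stress`, `nodal_vm`, `reactions`
#'   (data.frame), `equilibrium_residual`.
#' @export
solve_plate <- function(mesh, material, loadcase, thickness,
                        prescribed = NULL) {
  n <- nrow(mesh$nodes)
  K <- assemble_stiffness(mesh, material, thickness)
  f <- as.vector(t(loadcase$forces))
  if (is.null(prescribed)) {
    fixed <- fixed_dof_indices(loadcase, n)
    u <- numeric(2 * n)
  } else {
    fixed <- as.integer(names(prescribed))
    u <- numeric(2 * n)
    u[fixed] <- as.numeric(prescribed)
  }
  if (length(fixed) < 3) stop("insufficient constraints: at least three ",
                              "dofs are needed to remove rigid-body modes")
  free <- setdiff(seq_len(2L * n), fixed)
  rhs <- f[free] - as.vector(K[free, fixed, drop = FALSE] %*% u[fixed])
  sol <- tryCatch(
    Matrix::solve(K[free, free], rhs),
    error = function(e) stop("singular stiffness system (rigid-body mode ",
                             "not constrained?): ", conditionMessage(e)))
  u[free] <- as.vector(sol)
  resid <- as.vector(K %*% u) - f
  load_norm <- sqrt(sum(f^2))
  # global equilibrium: reactions (residual at fixed dofs) + applied = 0
  xd <- seq(1, 2 * n, 2); yd <- seq(2, 2 * n, 2)
  eq_res <- max(abs(sum(resid[intersect(fixed, xd)]) + sum(f[xd])),
                abs(sum(resid[intersect(fixed, yd)]) + sum(f[yd])))
  ux <- u[seq(1, 2 * n, 2)]; uy <- u[seq(2, 2 * n, 2)]
  # element stresses
  el <- mesh$elements
  nd <- mesh$nodes
  x <- matrix(nd[el, 1], ncol = 3); y <- matrix(nd[el, 2], ncol = 3)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  c_ <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  A <- 0.5 * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  uxm <- matrix(ux[el], ncol = 3); uym <- matrix(uy[el], ncol = 3)
  exx <- rowSums(b * uxm) / (2 * A)
  eyy <- rowSums(c_ * uym) / (2 * A)
  gxy <- (rowSums(c_ * uxm) + rowSums(b * uym)) / (2 * A)
  D <- plane_stress_D(material)
  sxx <- D[1, 1] * exx + D[1, 2] * eyy
  syy <- D[1, 2] * exx + D[1, 1] * eyy
  txy <- D[3, 3] * gxy
  # area-weighted nodal averaging
  wsum <- numeric(n); nsx <- numeric(n); nsy <- numeric(n); ntxy <- numeric(n)
  for (k in 1:3) {
    idx <- el[, k]
    wsum <- wsum + tab_add(idx, A, n)
    nsx <- nsx + tab_add(idx, A * sxx, n)
    nsy <- nsy + tab_add(idx, A * syy, n)
    ntxy <- ntxy + tab_add(idx, A * txy, n)
  }
  nsx <- nsx / wsum; nsy <- nsy / wsum; ntxy <- ntxy / wsum
  nvm <- sqrt(pmax(0, nsx^2 - nsx * nsy + nsy^2 + 3 * ntxy^2))
  fixed_nodes <- unique((fixed + 1L) %/% 2L)
  structure(list(
    displacements = cbind(ux, uy),
    element_stress = cbind(sxx = sxx, syy = syy, txy = txy),
    nodal_stress = cbind(sxx = nsx, syy = nsy, txy = ntxy),
    nodal_vm = nvm,
    reactions = data.frame(node = fixed_nodes,
                           rx = resid[2L * fixed_nodes - 1L],
                           ry = resid[2L * fixed_nodes]),
    equilibrium_residual = eq_res,
    load_norm = load_norm,
    scenario = loadcase$scenario %||% "custom"),
    class = "fea_result")
}

tab_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' @export
print.fea_result <- function(x, ...) {
  cat(sprintf("plane-stress FE solution (%s): %d nodes\n", x$scenario,
              nrow(x$displacements)))
  cat(sprintf("  max |u| %.4g mm, max nodal von Mises %.4g MPa\n",
              max(sqrt(rowSums(x$displacements^2))), max(x$nodal_vm)))
  cat(sprintf("  equilibrium residual %.3g (load norm %.3g)\n",
              x$equilibrium_residual, x$load_norm))
  invisible(x)
}

#' Export a solved mesh in legacy VTK ASCII format
#' @param mesh an `orbit_mesh`.
#' @param result a `fea_result`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_vtk <- function(mesh, result, path) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "plate FE result", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n),
               sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]),
               sprintf("CELLS %d %d", ne, 4 * ne),
               sprintf("3 %d %d %d", mesh$elements[, 1] - 1L,
                       mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L),
               sprintf("CELL_TYPES %d", ne),
               rep("5", ne),
               sprintf("POINT_DATA %d", n),
               "VECTORS displacement double",
               sprintf("%.9g %.9g 0", result$displacements[, 1],
                       result$displacements[, 2]),
               "SCALARS von_mises double 1", "LOOKUP_TABLE default",
               sprintf("%.9g", result$nodal_vm)), con)
  invisible(path)
}
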