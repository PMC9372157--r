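# Triangular meshing of rectangular plates, optionally pierced by an
# orbit-shaped hole. The pierced plate uses a structured, boundary-conforming
# ring mesh: node rays fan out from the plate centre, ring spacing is graded
# from target_edge/refine at the hole margin up to target_edge, and the
# angular resolution doubles outward whenever arcs outgrow the local size
# target. The construction is deterministic and exactly mirror-symmetric for
# mirror-symmetric holes.

new_mesh <- function(nodes, elements, boundary) {
  elements <- orient_elements(nodes, elements)
  structure(list(nodes = nodes, elements = elements, boundary = boundary),
            class = "orbit_mesh")
}

#' @export
print.orbit_mesh <- function(x, ...) {
  cat(sprintf("mesh: %d nodes, %d triangles, %d hole-margin nodes\n",
              nrow(x$nodes), nrow(x$elements),
              length(x$boundary$hole_margin)))
  invisible(x)
}

element_signed_areas <- function(nodes, elements) {
  x1 <- nodes[elements[, 1], 1]; y1 <- nodes[elements[, 1], 2]
  x2 <- nodes[elements[, 2], 1]; y2 <- nodes[elements[, 2], 2]
  x3 <- nodes[elements[, 3], 1]; y3 <- nodes[elements[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

orient_elements <- function(nodes, elements) {
  a <- element_signed_areas(nodes, elements)
  if (any(abs(a) < .Machine$double.eps))
    stop("degenerate (zero-area) element produced by the mesher")
  flip <- a < 0
  if (any(flip)) elements[flip, c(2, 3)] <- elements[flip, c(3, 2)]
  elements
}

#' Edge lengths of all element edges
#' @param mesh an `orbit_mesh`.
#' @return Numeric vector (3 entries per element; shared edges counted once
#'   per adjacent element).
#' @export
mesh_edge_lengths <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elements
  e <- rbind(el[, 1:2], el[, 2:3], el[, c(3, 1)])
  sqrt(rowSums((nd[e[, 1], , drop = FALSE] - nd[e[, 2], , drop = FALSE])^2))
}

#' Euler characteristic of the triangulation
#'
#' `V - E + F` over distinct vertices, distinct edges and triangles: 1 for a
#' disc (no hole), 0 for an annulus (plate pierced by one hole).
#'
#' @param mesh an `orbit_mesh`.
#' @return Integer.
#' @export
mesh_euler <- function(mesh) {
  el <- mesh$elements
  e <- rbind(el[, 1:2], el[, 2:3], el[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  n_edge <- nrow(unique(e))
  nrow(mesh$nodes) - n_edge + nrow(el)
}

#' Structured mesh of a plain rectangle
#'
#' @param w,h rectangle extent; the rectangle spans `[0, w] x [0, h]`.
#' @param nx,ny number of cells per direction.
#' @param pattern `"crossed"` (4 triangles per cell around a centre node;
#'   unbiased, used for bending-dominated checks) or `"diagonal"` (2 per
#'   cell).
#' @return An `orbit_mesh` with boundary tags `left`, `right`, `bottom`,
#'   `top` and an empty `hole_margin`.
#' @export
mesh_rect <- function(w, h, nx, ny, pattern = c("crossed", "diagonal")) {
  pattern <- match.arg(pattern)
  xs <- seq(0, w, length.out = nx + 1)
  ys <- seq(0, h, length.out = ny + 1)
  grid <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  id <- function(i, j) (j - 1L) * (nx + 1L) + i   # i along x, j along y
  quads <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  n1 <- id(quads$i, quads$j); n2 <- id(quads$i + 1L, quads$j)
  n3 <- id(quads$i + 1L, quads$j + 1L); n4 <- id(quads$i, quads$j + 1L)
  if (pattern == "diagonal") {
    nodes <- grid
    elements <- rbind(cbind(n1, n2, n3), cbind(n1, n3, n4))
  } else {
    ctr <- (grid[n1, ] + grid[n2, ] + grid[n3, ] + grid[n4, ]) / 4
    cid <- nrow(grid) + seq_len(nrow(quads))
    nodes <- rbind(grid, ctr)
    elements <- rbind(cbind(n1, n2, cid), cbind(n2, n3, cid),
                      cbind(n3, n4, cid), cbind(n4, n1, cid))
  }
  tol <- 1e-9 * max(w, h)
  boundary <- list(
    left = which(abs(nodes[, 1]) < tol),
    right = which(abs(nodes[, 1] - w) < tol),
    bottom = which(abs(nodes[, 2]) < tol),
    top = which(abs(nodes[, 2] - h) < tol),
    hole_margin = integer(0))
  new_mesh(nodes, as.matrix(elements), boundary)
}

# Distance from the plate centre to the square boundary along direction
# theta (square of side W centred at c0).
square_ray <- function(theta, W) {
  (W / 2) / pmax(abs(cos(theta)), abs(sin(theta)))
}

#' Mesh a plate pierced by an orbit-shaped hole
#'
#' @param geom plate geometry from [build_plate()].
#' @param target_edge target element edge length away from the hole
#'   (default `plate_w / 150`).
#' @param refine local refinement factor at the hole margin: the first ring
#'   of elements has edge length about `target_edge / refine`.
#' @return An `orbit_mesh`. Hole-margin nodes lie exactly on the hole
#'   polygon; outer-ring nodes lie exactly on the plate boundary.
#' @export
mesh_plate <- function(geom, target_edge = geom$plate_w / 150, refine = 3) {
  W <- geom$plate_w
  c0 <- c(W / 2, geom$plate_h / 2)
  poly <- geom$hole$vertices
  h_near <- target_edge / refine
  h_far <- target_edge
  perim <- polygon_perimeter(poly)
  N0 <- 2^max(5, ceiling(log2(perim / h_near)))
  r_hole_at <- function(th) {
    vapply(th, function(a) {
      hits <- ray_polygon_hits(poly, c0, a)
      if (!length(hits))
        stop("hole polygon not star-shaped from the plate centre ",
             "(no boundary crossing at angle ", round(a * 180 / pi, 2),
             " deg); geometry: ", nrow(poly), " vertices, area ",
             signif(polygon_area(poly), 6))
      max(hits)
    }, numeric(1))
  }
  nodes <- list(); n_nodes <- 0L
  add_nodes <- function(xy) {
    nodes[[length(nodes) + 1L]] <<- xy
    idx <- n_nodes + seq_len(nrow(xy))
    n_nodes <<- n_nodes + nrow(xy)
    idx
  }
  # rings blend from the hole outline to an intermediate circle (radius rc,
  # reached at normalized position tm), then from that circle out to the
  # square boundary; mid-annulus rings are round, so element sizes away from
  # the hole do not echo the hole shape
  th64 <- seq(0, 2 * pi, length.out = 65)[-65]
  ring_radius <- function(th, t) {
    rh <- r_hole_at(th)
    ro <- square_ray(th, W)
    rc <- ring_rc
    if (t <= ring_tm) rh + (t / ring_tm) * (rc - rh)
    else rc + ((t - ring_tm) / (1 - ring_tm)) * (ro - rc)
  }
  ring_nodes <- function(Nk, t) {
    th <- (seq_len(Nk) - 1L) * 2 * pi / Nk
    r <- ring_radius(th, t)
    add_nodes(cbind(c0[1] + r * cos(th), c0[2] + r * sin(th)))
  }
  elements <- list()
  add_tris <- function(m) elements[[length(elements) + 1L]] <<- m
  # connect two rings with equal angular count: split quads on the shorter
  # diagonal; near-equal diagonals (symmetry axis) get a centroid 4-split
  connect_equal <- function(ia, ib) {
    Nk <- length(ia)
    j2 <- c(seq_len(Nk)[-1], 1L)
    p0 <- ia; p1 <- ia[j2]; q0 <- ib; q1 <- ib[j2]
    nd <- do.call(rbind, nodes)
    d1 <- rowSums((nd[p0, ] - nd[q1, ])^2)
    d2 <- rowSums((nd[p1, ] - nd[q0, ])^2)
    tie <- abs(d1 - d2) < 1e-12 * (d1 + d2)
    use1 <- d1 <= d2 & !tie
    use2 <- !use1 & !tie
    if (any(use1))
      add_tris(rbind(cbind(p0[use1], p1[use1], q1[use1]),
                     cbind(p0[use1], q1[use1], q0[use1])))
    if (any(use2))
      add_tris(rbind(cbind(p0[use2], p1[use2], q0[use2]),
                     cbind(p1[use2], q1[use2], q0[use2])))
    if (any(tie)) {
      ctr <- (nd[p0[tie], , drop = FALSE] + nd[p1[tie], , drop = FALSE] +
              nd[q0[tie], , drop = FALSE] + nd[q1[tie], , drop = FALSE]) / 4
      cid <- add_nodes(ctr)
      add_tris(rbind(cbind(p0[tie], p1[tie], cid),
                     cbind(p1[tie], q1[tie], cid),
                     cbind(q1[tie], q0[tie], cid),
                     cbind(q0[tie], p0[tie], cid)))
    }
  }
  # inner ring of Nk nodes to outer ring of 2*Nk nodes
  connect_double <- function(ia, ib) {
    Nk <- length(ia)
    j2 <- c(seq_len(Nk)[-1], 1L)
    p0 <- ia; p1 <- ia[j2]
    q0 <- ib[2L * seq_len(Nk) - 1L]
    qm <- ib[2L * seq_len(Nk)]
    q1 <- ib[c(2L * seq_len(Nk)[-1] - 1L, 1L)]
    add_tris(rbind(cbind(p0, qm, q0), cbind(p0, p1, qm), cbind(p1, q1, qm)))
  }
  # inner ring of 2*Nk nodes to outer ring of Nk nodes
  connect_halve <- function(ia, ib) {
    Nk <- length(ib)
    f0 <- ia[2L * seq_len(Nk) - 1L]
    fm <- ia[2L * seq_len(Nk)]
    f1 <- ia[c(2L * seq_len(Nk)[-1] - 1L, 1L)]
    c0 <- ib
    c1 <- ib[c(seq_len(Nk)[-1], 1L)]
    add_tris(rbind(cbind(f0, fm, c0), cbind(fm, c1, c0), cbind(fm, f1, c1)))
  }
  rh64 <- r_hole_at(th64)
  ro64 <- square_ray(th64, W)
  r_mean_hole <- mean(rh64)
  gap_mean <- mean(ro64) - r_mean_hole
  # intermediate circle: just outside the hole's largest radius, and at most
  # halfway to the nearest plate edge
  ring_rc <- min(1.15 * max(rh64), 0.5 * (max(rh64) + min(ro64)))
  ring_rc <- max(ring_rc, 1.02 * max(rh64))
  if (ring_rc >= min(ro64))
    stop("hole leaves no room for a conforming ring mesh (hole radius ",
         signif(max(rh64), 4), " vs plate half-width ", signif(min(ro64), 4),
         ")")
  ring_tm <- (ring_rc - r_mean_hole) / gap_mean
  Nk <- N0
  cur <- ring_nodes(Nk, 0)
  hole_margin <- cur
  t <- 0; h_k <- h_near
  repeat {
    # keep radial steps commensurate with the local arc spacing so element
    # aspect ratios stay bounded everywhere
    arc_cur <- (r_mean_hole + t * gap_mean) * 2 * pi / Nk
    h_eff <- min(h_k, 1.4 * arc_cur)
    dt <- h_eff / gap_mean
    t_next <- t + dt
    if (t_next >= 1 - 0.45 * dt) t_next <- 1
    r_mean <- r_mean_hole + t_next * gap_mean
    arc_next <- r_mean * 2 * pi / Nk
    if (arc_next > 1.45 * h_eff && Nk < 16384L) {
      Nk <- Nk * 2L
    } else if (arc_next < 0.55 * h_k && Nk >= 64L) {
      Nk <- Nk %/% 2L
    }
    nxt <- ring_nodes(Nk, t_next)
    if (length(nxt) == 2L * length(cur)) {
      connect_double(cur, nxt)
    } else if (length(nxt) == length(cur)) {
      connect_equal(cur, nxt)
    } else if (2L * length(nxt) == length(cur)) {
      connect_halve(cur, nxt)
    } else {
      stop("mesh grading failure: angular count jumped from ",
           length(cur), " to ", length(nxt))
    }
    cur <- nxt
    t <- t_next
    h_k <- min(h_far, h_k * 1.25)
    if (t >= 1) break
  }
  nd <- do.call(rbind, nodes)
  el <- do.call(rbind, elements)
  tol <- 1e-9 * W
  outer <- cur
  boundary <- list(
    left = outer[abs(nd[outer, 1]) < tol],
    right = outer[abs(nd[outer, 1] - W) < tol],
    bottom = outer[abs(nd[outer, 2]) < tol],
    top = outer[abs(nd[outer, 2] - geom$plate_h) < tol],
    hole_margin = hole_margin)
  m <- new_mesh(nd, el, boundary)
  a <- element_signed_areas(m$nodes, m$elements)
  if (min(a) <= 0) stop("mesh contains inverted elements; the hole is too ",
                        "far from star-shaped for the ring mesher")
  m
}

#' Export a mesh in Gmsh MSH 2.2 ASCII format
#' @param mesh an `orbit_mesh`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_msh <- function(mesh, path) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elements)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(n),
               sprintf("%d %.9g %.9g 0", seq_len(n), mesh$nodes[, 1],
                       mesh$nodes[, 2]),
               "$EndNodes", "$Elements", as.character(ne),
               sprintf("%d 2 2 0 1 %d %d %d", seq_len(ne),
                       mesh$elements[, 1], mesh$elements[, 2],
                       mesh$elements[, 3]),
               "$EndElements"), con)
  invisible(path)
}
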