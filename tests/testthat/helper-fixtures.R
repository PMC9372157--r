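# Shared fixtures, built lazily once per test run and cached, so expensive
# objects (populations, meshes, FE solutions) are not recomputed per file.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fx_population_small <- function() fixture("pop_small", {
  generate_population(n = 60, seed = 11, beta_size = 2, beta_carn = 1,
                      noise_sd = 0.01)
})

fx_landmarks_small <- function() fixture("lms_small", {
  landmark_outlines(fx_population_small())
})

fx_gpa_small <- function() fixture("gpa_small", {
  gpa(fx_landmarks_small())
})

fx_model_small <- function() fixture("model_small", {
  morphospace_pca(fx_gpa_small())
})

fx_material <- function() fe_material()

# coarse companion plate + uniform-traction solution, reused by SCF tests
fx_companion <- function() fixture("companion", {
  m <- mesh_rect(10, 10, 60, 60, pattern = "diagonal")
  sol <- solve_plate(m, fx_material(), make_traction_case(m, "top", 1, 1), 1)
  list(mesh = m, sol = sol)
})

# brute-force horizontal slice widths of a polygon, implemented from
# scratch (independent oracle for the keyhole waist contract): returns the
# interior-local-minimum / global-max width ratio and the number of interior
# local minima of the width profile
slice_width_scan <- function(v, ns = 1000) {
  ax <- v[, 1]; ay <- v[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  ys <- seq(min(ay) + 1e-6 * diff(range(ay)),
            max(ay) - 1e-6 * diff(range(ay)), length.out = ns)
  w <- vapply(ys, function(y) {
    cross <- (ay > y) != (by > y)
    if (sum(cross) < 2) return(0)
    xs <- ax[cross] + (y - ay[cross]) * (bx[cross] - ax[cross]) /
      (by[cross] - ay[cross])
    max(xs) - min(xs)
  }, numeric(1))
  # interior local minima, tolerant of flat plateaus on symmetric grids
  s <- sign(diff(w))
  nz <- which(s != 0)
  sv <- s[nz]
  trans <- which(sv[-length(sv)] == -1 & sv[-1] == 1)
  locmin <- nz[trans] + 1
  locmin <- locmin[w[locmin] > 0]
  list(n_min = length(locmin),
       ratio = if (length(locmin)) min(w[locmin]) / max(w) else NA_real_)
}

# minimum distance from each point to a polygon boundary (independent check
# of mesh/boundary conformity)
dist_to_polygon <- function(pts, poly) {
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  e <- b - a
  len2 <- rowSums(e^2)
  vapply(seq_len(nrow(pts)), function(k) {
    p <- pts[k, ]
    t <- ((p[1] - a[, 1]) * e[, 1] + (p[2] - a[, 2]) * e[, 2]) / len2
    t <- pmin(pmax(t, 0), 1)
    qx <- a[, 1] + t * e[, 1]; qy <- a[, 2] + t * e[, 2]
    sqrt(min((qx - p[1])^2 + (qy - p[2])^2))
  }, numeric(1))
}

rotmat <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}
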