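# Parametric orbit-outline generators: the theoretical design set spanning
# circular -> elliptical -> constricted (figure-of-eight) -> wedge
# morphologies, and a covariate-linked synthetic population standing in for
# a digitised fossil sample.

SHAPE_FAMILIES <- c("circle", "ellipse", "keyhole", "wedge")

#' Parameter set for a single theoretical orbit shape
#'
#' @param family one of `"circle"`, `"ellipse"`, `"keyhole"`, `"wedge"`.
#' @param size maximum dimension of the generated outline (model units),
#'   measured as the polygon diameter (maximum caliper extent).
#' @param aspect dorsoventral / anteroposterior extent ratio. Keyholes must
#'   have `aspect >= 1` (use `tilt` for horizontal orientations).
#' @param waist constriction fraction in `[0, 1)`: the narrowest width of a
#'   keyhole equals `(1 - waist)` times its widest width. Ignored for other
#'   families.
#' @param waist_pos relative dorsoventral position of the narrowest point,
#'   in `(0, 1)` (0.5 = centred).
#' @param tilt rotation of the finished outline, degrees counter-clockwise.
#' @param n_vertices polygon resolution (even, >= 64).
#' @return A `shape_params` list.
#' @export
shape_params <- function(family, size = 1000, aspect = NULL, waist = 0,
                         waist_pos = 0.5, tilt = 0, n_vertices = 128) {
  family <- match.arg(family, SHAPE_FAMILIES)
  if (is.null(aspect)) aspect <- if (family == "keyhole") 1.7 else 1
  if (size <= 0) stop("size must be > 0")
  if (aspect <= 0) stop("aspect must be > 0")
  if (waist < 0 || waist >= 1) stop("waist must lie in [0, 1)")
  if (waist_pos <= 0 || waist_pos >= 1) stop("waist_pos must lie in (0, 1)")
  if (n_vertices < 64) stop("n_vertices must be >= 64")
  n_vertices <- as.integer(n_vertices)
  if (n_vertices %% 2L == 1L) n_vertices <- n_vertices + 1L
  if (family == "keyhole" && aspect < 1)
    stop("keyhole with aspect = ", aspect, " < 1 is not supported; ",
         "keyholes are built dorsoventrally elongate - use tilt for ",
         "horizontal orientations")
  structure(list(family = family, size = size, aspect = aspect,
                 waist = waist, waist_pos = waist_pos, tilt = tilt,
                 n_vertices = n_vertices),
            class = "shape_params")
}

# Unit keyhole boundary: two circular lobes of width 1 joined by straight
# flanks (a stadium envelope), with the waist cut by a narrow Gaussian dip in
# the width profile. The realised narrowest/widest width ratio equals
# (1 - waist) because the dip is localised inside the flat flank zone.
keyhole_vertices <- function(aspect, waist, waist_pos, n) {
  H <- aspect                         # unit width, height = aspect
  yc <- H / 2 - 0.5                   # flat-zone half-extent (>= 0)
  s <- 0.09 * H                       # dip half-width
  yw <- (waist_pos - 0.5) * 2 * yc    # dip centre within the flat zone
  width_at <- function(y) {
    a <- pmax(0, abs(y) - yc)
    env <- 2 * sqrt(pmax(0, 0.25 - a^2))
    env * (1 - waist * exp(-((y - yw) / s)^2))
  }
  m <- n %/% 2L
  phi <- seq(-pi / 2, pi / 2, length.out = m + 1L)
  yr <- (H / 2) * sin(phi)                       # bottom tip -> top tip
  right <- cbind(width_at(yr) / 2, yr)
  yl <- yr[seq(m, 2L)]                           # top -> bottom, open ends
  left <- cbind(-width_at(yl) / 2, yl)
  rbind(right, left)
}

ellipse_vertices <- function(aspect, n) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(0.5 * cos(t), (aspect / 2) * sin(t))
}

# Replace polygon corners by tangent circular arcs of radius rc.
round_corners <- function(pts, rc, arc_pts = 12L) {
  n <- nrow(pts)
  out <- list()
  for (i in seq_len(n)) {
    p <- pts[i, ]
    prev <- pts[if (i == 1) n else i - 1, ]
    nxt <- pts[if (i == n) 1 else i + 1, ]
    u <- (p - prev) / sqrt(sum((p - prev)^2))   # incoming direction
    v <- (nxt - p) / sqrt(sum((nxt - p)^2))     # outgoing direction
    cosa <- sum(-u * v)
    alpha <- acos(pmin(1, pmax(-1, cosa)))      # interior angle
    d <- rc / tan(alpha / 2)
    t1 <- p - u * d                             # tangent point, incoming edge
    t2 <- p + v * d                             # tangent point, outgoing edge
    bis <- (v - u); bis <- bis / sqrt(sum(bis^2))
    ctr <- p + bis * rc / sin(alpha / 2)
    a1 <- atan2(t1[2] - ctr[2], t1[1] - ctr[1])
    a2 <- atan2(t2[2] - ctr[2], t2[1] - ctr[1])
    # sweep the short way round
    da <- (a2 - a1) %% (2 * pi)
    if (da > pi) da <- da - 2 * pi
    aa <- a1 + seq(0, da, length.out = arc_pts)
    out[[i]] <- cbind(ctr[1] + rc * cos(aa), ctr[2] + rc * sin(aa))
  }
  do.call(rbind, out)
}

wedge_vertices <- function(aspect, n) {
  H <- aspect
  tri <- rbind(c(0, -H / 2), c(0.5, H / 2), c(-0.5, H / 2))  # apex ventral
  rc <- 0.05 * max(1, sqrt(H^2 + 0.25))
  resample_polygon(round_corners(tri, rc), n)
}

#' Generate one theoretical orbit outline
#'
#' Builds a closed, simple, counter-clockwise polygon of the requested family
#' and rescales it so that its maximum dimension equals `params$size` exactly.
#'
#' @param params a [shape_params()] object.
#' @param ... covariates forwarded to [orbit_outline()] (`taxon`, `group`,
#'   `diet`, `skull_length`, `time_bin`, `view`).
#' @return An [orbit_outline()].
#' @export
make_outline <- function(params, ...) {
  stopifnot(inherits(params, "shape_params"))
  v <- switch(params$family,
    circle  = ellipse_vertices(1, params$n_vertices),
    ellipse = ellipse_vertices(params$aspect, params$n_vertices),
    keyhole = keyhole_vertices(params$aspect, params$waist,
                               params$waist_pos, params$n_vertices),
    wedge   = wedge_vertices(params$aspect, params$n_vertices))
  if (params$family == "ellipse" && params$aspect < 1) {
    # wide ellipse: widen x instead of shrinking y, then rescale below
    v <- cbind(v[, 1] / params$aspect, v[, 2] / params$aspect)
  }
  v <- v * (params$size / polygon_diameter(v))
  if (params$tilt != 0) {
    a <- params$tilt * pi / 180
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    v <- v %*% t(R)
  }
  v <- sweep(v, 2, polygon_centroid(v))
  out <- tryCatch(orbit_outline(ensure_ccw(v), ...), error = function(e)
    stop("shape_params(family=", params$family, ", aspect=", params$aspect,
         ", waist=", params$waist, ", waist_pos=", params$waist_pos,
         ") produced an invalid outline: ", conditionMessage(e)))
  out
}

# Canonical design table for the theoretical set, ordered so that truncation
# keeps at least one circle, ellipse and keyhole first.
theoretical_table <- function() {
  r <- function(id, family, aspect = NA, waist = 0, waist_pos = 0.5,
                tilt = 0)
    data.frame(id = id, family = family, aspect = aspect, waist = waist,
               waist_pos = waist_pos, tilt = tilt,
               stringsAsFactors = FALSE)
  rbind(
    r("circle",          "circle"),
    r("ellipse_tall",    "ellipse", 1.7),
    r("keyhole_w50",     "keyhole", 1.7, 0.5),
    r("wedge",           "wedge",   1.0),
    r("ellipse_wide",    "ellipse", 1 / 1.7),
    r("keyhole_w30",     "keyhole", 1.5, 0.3),
    r("keyhole_w70",     "keyhole", 1.9, 0.7),
    r("ellipse_a13",     "ellipse", 1.3),
    r("ellipse_a25",     "ellipse", 2.5),
    r("ellipse_flat",    "ellipse", 0.4),
    r("ellipse_tilt_p45","ellipse", 1.7, tilt = 45),
    r("ellipse_tilt_m45","ellipse", 1.7, tilt = -45),
    r("keyhole_tilt_p30","keyhole", 1.7, 0.5, tilt = 30),
    r("keyhole_tilt_m30","keyhole", 1.7, 0.5, tilt = -30),
    r("keyhole_low",     "keyhole", 1.7, 0.5, waist_pos = 0.32),
    r("keyhole_high",    "keyhole", 1.7, 0.5, waist_pos = 0.68),
    r("keyhole_w60_a22", "keyhole", 2.2, 0.6),
    r("wedge_tall",      "wedge",   1.4),
    r("wedge_flat",      "wedge",   0.8),
    r("wedge_inverted",  "wedge",   1.0, tilt = 180),
    r("keyhole_w85",     "keyhole", 2.0, 0.85))
}

#' The theoretical orbit-shape design set
#'
#' A deterministic set of outlines spanning the observed orbit-shape
#' diversity: circular, elliptical (tall, wide, tilted), constricted
#' figure-of-eight keyholes of varying waist depth, position and orientation,
#' and ventrally tapering wedges. The default set has 21 members.
#'
#' @param n_shapes number of shapes (3..21). Truncation preserves family
#'   coverage in the order circle, ellipse, keyhole, wedge.
#' @param size maximum dimension of each outline (model units).
#' @param n_vertices polygon resolution per outline.
#' @return Named list of [orbit_outline()] objects.
#' @export
theoretical_set <- function(n_shapes = 21, size = 1000, n_vertices = 128) {
  tab <- theoretical_table()
  if (n_shapes < 3) stop("n_shapes must be >= 3")
  if (n_shapes > nrow(tab))
    stop("the canonical design set has only ", nrow(tab), " shapes")
  tab <- tab[seq_len(n_shapes), ]
  out <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab[i, ]
    asp <- if (is.na(p$aspect)) NULL else p$aspect
    make_outline(shape_params(p$family, size = size, aspect = asp,
                              waist = p$waist, waist_pos = p$waist_pos,
                              tilt = p$tilt, n_vertices = n_vertices),
                 taxon = p$id)
  })
  names(out) <- tab$id
  out
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic specimen population
#'
#' Emulates the empirical pattern that orbit non-circularity increases with
#' skull size and carnivory: each specimen's waist (constriction) is a
#' bounded logistic function of a linear predictor in the z-scored log skull
#' length and a carnivory indicator,
#' `waist = clip(2 * plogis(beta_size * z + beta_carn * carnivore) - 1 +
#' noise, 0, 0.95)`, so a zero linear predictor yields an exactly circular
#' orbit. Outline elongation grows with the waist (aspect `1 + waist`), as in
#' real constricted orbits.
#'
#' @param n number of specimens (>= 2).
#' @param seed RNG seed; the global RNG state is restored on exit.
#' @param beta_size effect of z-scored log skull length on the waist
#'   predictor.
#' @param beta_carn additive carnivory effect on the waist predictor.
#' @param noise_sd Gaussian noise SD added to the realised waist.
#' @param size_range skull-length range in mm, sampled log-uniformly.
#' @param n_vertices polygon resolution per outline.
#' @return List of [orbit_outline()]s with a `covariates` attribute
#'   (data.frame: taxon, group, diet, skull_length_mm, time_bin, family,
#'   waist).
#' @export
generate_population <- function(n = 410, seed = 1, beta_size = 2,
                                beta_carn = 1, noise_sd = 0.02,
                                size_range = c(50, 1500),
                                n_vertices = 128) {
  if (n < 2) stop("n must be >= 2 (downstream Procrustes needs >= 2)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(size_range) != 2 || any(size_range <= 0) ||
      size_range[1] >= size_range[2])
    stop("size_range must be an increasing positive pair (mm)")
  with_seed(seed, {
    skull <- exp(stats::runif(n, log(size_range[1]), log(size_range[2])))
    diet <- sample(DIET_LEVELS, n, replace = TRUE,
                   prob = c(0.45, 0.15, 0.40))
    group <- sample(ORBIT_GROUPS, n, replace = TRUE,
                    prob = c(0.12, 0.15, 0.08, 0.35, 0.15, 0.15))
    bins <- c("Early Triassic", "Middle Triassic", "Late Triassic",
              "Early Jurassic", "Late Jurassic", "Early Cretaceous",
              "Late Cretaceous")
    time_bin <- sample(bins, n, replace = TRUE)
    z <- as.numeric(scale(log(skull)))
    eta <- beta_size * z + beta_carn * (diet == "carnivore")
    waist <- 2 * stats::plogis(eta) - 1 + stats::rnorm(n, 0, noise_sd)
    waist <- pmin(pmax(waist, 0), 0.9499)
    taxon <- sprintf("taxon_%04d", seq_len(n))
    outlines <- lapply(seq_len(n), function(i) {
      fam <- if (waist[i] > 0) "keyhole" else "circle"
      make_outline(
        shape_params(fam, size = skull[i] * 0.25,
                     aspect = if (fam == "keyhole") 1 + waist[i] else 1,
                     waist = waist[i], n_vertices = n_vertices),
        taxon = taxon[i],
        group = group[i],
        diet = diet[i],
        skull_length = skull[i],
        time_bin = time_bin[i],
        view = if (group[i] == "Crocodylomorpha") "dorsal" else "lateral")
    })
    names(outlines) <- taxon
    attr(outlines, "covariates") <- data.frame(
      taxon = taxon, group = group, diet = diet,
      skull_length_mm = skull, time_bin = time_bin,
      family = ifelse(waist > 0, "keyhole", "circle"),
      waist = waist, stringsAsFactors = FALSE)
    for (i in seq_len(n)) attr(outlines[[i]], "waist") <- waist[i]
    outlines
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Covariate table of a generated population
#' @param population result of [generate_population()].
#' @return data.frame of per-specimen covariates incl. the realised waist.
#' @export
population_covariates <- function(population) {
  cv <- attr(population, "covariates")
  if (is.null(cv)) stop("population carries no covariate attribute")
  cv
}
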