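# The orbit_outline S3 class: a closed 2-D outline of the orbital opening
# plus specimen covariates (taxon, group, diet, skull length, time bin).

ORBIT_GROUPS <- c("Archosauromorpha", "Pseudosuchia", "Dinosauromorpha",
                  "Dinosauria", "Pterosauria", "Crocodylomorpha")
DIET_LEVELS <- c("herbivore", "omnivore", "carnivore")

#' Construct an orbit outline
#'
#' An ordered, closed, counter-clockwise simple polygon describing the margin
#' of the orbital opening, together with the specimen covariates carried
#' through the morphometric and biomechanical stages.
#'
#' @param vertices n x 2 numeric matrix (n >= 32), implicitly closed.
#' @param taxon specimen label.
#' @param view `"lateral"` or `"dorsal"` (metadata only; dorsal is used for
#'   crocodylomorph-style outlines).
#' @param group taxonomic group, one of
#'   Archosauromorpha, Pseudosuchia, Dinosauromorpha, Dinosauria, Pterosauria,
#'   Crocodylomorpha.
#' @param diet `"herbivore"`, `"omnivore"` or `"carnivore"`.
#' @param skull_length skull length in mm (> 0).
#' @param time_bin stratigraphic bin label.
#' @return An object of class `orbit_outline`.
#' @export
orbit_outline <- function(vertices, taxon = "unnamed", view = "lateral",
                          group = "Archosauromorpha", diet = "omnivore",
                          skull_length = 100, time_bin = "unspecified") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2) stop("vertices must be an n x 2 matrix")
  if (nrow(vertices) < 32) stop("an orbit outline needs >= 32 vertices")
  if (!view %in% c("lateral", "dorsal")) stop("view must be lateral or dorsal")
  if (!group %in% ORBIT_GROUPS)
    stop("unknown group '", group, "'; expected one of: ",
         paste(ORBIT_GROUPS, collapse = ", "))
  if (!diet %in% DIET_LEVELS)
    stop("unknown diet '", diet, "'; expected one of: ",
         paste(DIET_LEVELS, collapse = ", "))
  if (!is.numeric(skull_length) || skull_length <= 0)
    stop("skull_length must be > 0 (mm)")
  vertices <- ensure_ccw(vertices)
  if (abs(polygon_area(vertices)) <= 0) stop("outline has zero area")
  if (!polygon_is_simple(vertices)) stop("outline polygon self-intersects")
  structure(list(vertices = vertices, taxon = taxon, view = view,
                 group = group, diet = diet, skull_length = skull_length,
                 time_bin = time_bin),
            class = "orbit_outline")
}

#' @export
print.orbit_outline <- function(x, ...) {
  cat(sprintf("orbit outline '%s' (%s, %s view)\n", x$taxon, x$group, x$view))
  cat(sprintf("  %d vertices, area %.4g, max dimension %.4g\n",
              nrow(x$vertices), polygon_area(x$vertices),
              polygon_diameter(x$vertices)))
  cat(sprintf("  diet %s, skull length %.1f mm, time bin %s\n",
              x$diet, x$skull_length, x$time_bin))
  invisible(x)
}

#' Write / read outlines as plain-text polygon files
#'
#' One `x y` pair per line; covariates stored as `#key: value` header
#' comments, so the files remain readable by generic point-list tools.
#'
#' @param outline an `orbit_outline`.
#' @param path file path.
#' @return `read_outline` returns an `orbit_outline`; `write_outline` its
#'   path, invisibly.
#' @export
write_outline <- function(outline, path) {
  hdr <- sprintf("#%s: %s",
                 c("taxon", "view", "group", "diet", "skull_length_mm",
                   "time_bin"),
                 c(outline$taxon, outline$view, outline$group, outline$diet,
                   format(outline$skull_length, digits = 12),
                   outline$time_bin))
  body <- sprintf("%.9f %.9f", outline$vertices[, 1], outline$vertices[, 2])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_outline
#' @export
read_outline <- function(path) {
  ln <- readLines(path)
  hdr <- grep("^#", ln, value = TRUE)
  body <- ln[!grepl("^#", ln) & nzchar(trimws(ln))]
  kv <- sub("^#([^:]+):\\s*(.*)$", "\\1\x01\\2", hdr)
  keys <- sub("\x01.*$", "", kv); vals <- sub("^.*\x01", "", kv)
  names(vals) <- keys
  xy <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  get <- function(k, default) if (k %in% keys) vals[[k]] else default
  orbit_outline(xy,
                taxon = get("taxon", "unnamed"),
                view = get("view", "lateral"),
                group = get("group", "Archosauromorpha"),
                diet = get("diet", "omnivore"),
                skull_length = as.numeric(get("skull_length_mm", "100")),
                time_bin = get("time_bin", "unspecified"))
}

#' Export an outline as an SVG path for visual inspection
#' @param outline an `orbit_outline`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_outline_svg <- function(outline, path) {
  v <- outline$vertices
  rng <- apply(v, 2, range)
  pad <- 0.05 * max(rng[2, ] - rng[1, ])
  # SVG y runs downwards; flip so dorsal stays up
  d <- paste0("M ", paste(sprintf("%.3f,%.3f", v[, 1], -v[, 2]),
                          collapse = " L "), " Z")
  writeLines(c(
    sprintf(paste0("<svg xmlns='http://www.w3.org/2000/svg' viewBox=",
                   "'%.3f %.3f %.3f %.3f'>"),
            rng[1, 1] - pad, -rng[2, 2] - pad,
            diff(rng[, 1]) + 2 * pad, diff(rng[, 2]) + 2 * pad),
    sprintf("  <path d='%s' fill='none' stroke='black' stroke-width='%.3f'/>",
            d, pad / 10),
    "</svg>"), path)
  invisible(path)
}
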