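# Stress concentration factors: peak von Mises stress along the hole margin
# relative to a reference stress taken from an identically loaded, unpierced
# companion plate sampled at the plate centre.

reference_component <- function(scenario) {
  switch(scenario,
    dv_compression = "syy", traction_y = "syy",
    ap_compression = "sxx", traction_x = "sxx",
    anterior_shear = "principal", dorsal_shear = "principal",
    stop("unknown scenario '", scenario, "'"))
}

node_nearest <- function(mesh, p) {
  which.min((mesh$nodes[, 1] - p[1])^2 + (mesh$nodes[, 2] - p[2])^2)
}

#' Reference stress of a companion (unpierced) plate
#'
#' Samples the nodal stress at the plate centre: the magnitude of the
#' load-parallel normal component for the compression scenarios, the maximum
#' principal stress magnitude for the shear scenarios.
#'
#' @param result `fea_result` of the unpierced companion plate.
#' @param mesh the companion mesh.
#' @param scenario scenario name.
#' @param centre plate centre coordinates.
#' @return Reference stress (MPa, positive).
#' @export
reference_stress <- function(result, mesh, scenario,
                             centre = colMeans(apply(mesh$nodes, 2, range))) {
  i <- node_nearest(mesh, centre)
  s <- result$nodal_stress[i, ]
  comp <- reference_component(scenario)
  ref <- switch(comp,
    syy = abs(s[["syy"]]),
    sxx = abs(s[["sxx"]]),
    principal = {
      m <- (s[["sxx"]] + s[["syy"]]) / 2
      r <- sqrt(((s[["sxx"]] - s[["syy"]]) / 2)^2 + s[["txy"]]^2)
      max(abs(m + r), abs(m - r))
    })
  if (ref < .Machine$double.eps)
    stop("degenerate load: companion reference stress is zero")
  ref
}

#' Stress concentration factor of a pierced plate
#'
#' @param result `fea_result` of the pierced plate.
#' @param mesh the pierced mesh (hole-margin nodes tagged); for an unpierced
#'   plate the peak is taken at the plate centre.
#' @param ref_result,ref_mesh companion solution and mesh of the unpierced
#'   plate under the same loading.
#' @param scenario scenario name (defaults to the result's).
#' @return An `scf_result`: `peak_stress`, `reference_stress`, `factor`.
#' @export
stress_concentration <- function(result, mesh, ref_result, ref_mesh,
                                 scenario = result$scenario) {
  margin <- mesh$boundary$hole_margin
  peak <- if (length(margin)) max(result$nodal_vm[margin])
          else result$nodal_vm[node_nearest(
            mesh, colMeans(apply(mesh$nodes, 2, range)))]
  ref <- reference_stress(ref_result, ref_mesh, scenario)
  structure(list(peak_stress = peak, reference_stress = ref,
                 factor = peak / ref, scenario = scenario),
            class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("SCF (%s): peak %.4g / reference %.4g = %.3f\n",
              x$scenario, x$peak_stress, x$reference_stress, x$factor))
  invisible(x)
}

#' Stress concentration factors for a set of shapes and scenarios
#'
#' For each shape: centres and scales the outline into the plate
#' ([build_plate()]), meshes it once, applies the quasi-homothetic per-load
#' force (1 N for the circular reference model, scaled by load-bearing area
#' for the rest), solves each scenario, and reports the SCF against an
#' unpierced companion plate solved once per scenario (scaled by linearity).
#' Per-shape failures are recorded in the `error` column and the run
#' continues.
#'
#' @param shapes named list of [orbit_outline()]s.
#' @param scenarios character vector of scenarios.
#' @param hole_fraction hole maximum dimension / plate width.
#' @param plate_w plate width (mm).
#' @param target_edge mesh size target (mm).
#' @param refine hole-margin refinement factor.
#' @param material a [fe_material()].
#' @param ref_force per-load force of the circular reference model (N).
#' @return data.frame: shape_id, family (best-effort from the name),
#'   scenario, force_per_load, peak_mpa, ref_mpa, scf, error.
#' @export
performance_table <- function(shapes, scenarios = SCENARIOS,
                              hole_fraction = 0.4, plate_w = 10,
                              target_edge = plate_w / 100, refine = 3,
                              material = fe_material(), ref_force = 1) {
  stopifnot(length(shapes) >= 1)
  circle <- make_outline(shape_params("circle", size = 1000))
  ref_geom <- build_plate(circle, hole_fraction, plate_w)
  companion_geom <- build_plate(NULL, hole_fraction, plate_w)
  ncell <- max(10L, round(plate_w / target_edge))
  comp_mesh <- mesh_rect(plate_w, plate_w, ncell, ncell,
                         pattern = "diagonal")
  comp_sol <- lapply(scenarios, function(sc)
    solve_plate(comp_mesh, material,
                make_load_case(comp_mesh, sc, force_per_load = 1),
                companion_geom$thickness))
  names(comp_sol) <- scenarios
  rows <- list()
  for (sid in names(shapes)) {
    row_err <- function(msg) data.frame(
      shape_id = sid, scenario = scenarios, force_per_load = NA_real_,
      peak_mpa = NA_real_, ref_mpa = NA_real_, scf = NA_real_,
      error = msg, stringsAsFactors = FALSE)
    res <- tryCatch({
      geom <- build_plate(shapes[[sid]], hole_fraction, plate_w)
      msh <- mesh_plate(geom, target_edge = target_edge, refine = refine)
      Fs <- scale_loads(ref_geom, geom, ref_force)
      do.call(rbind, lapply(scenarios, function(sc) {
        lc <- make_load_case(msh, sc, force_per_load = Fs)
        sol <- solve_plate(msh, material, lc, geom$thickness)
        # companion solved at unit load; stresses scale linearly with force
        ref <- Fs * reference_stress(comp_sol[[sc]], comp_mesh, sc)
        margin <- msh$boundary$hole_margin
        peak <- max(sol$nodal_vm[margin])
        data.frame(shape_id = sid, scenario = sc, force_per_load = Fs,
                   peak_mpa = peak, ref_mpa = ref, scf = peak / ref,
                   error = NA_character_, stringsAsFactors = FALSE)
      }))
    }, error = function(e) row_err(conditionMessage(e)))
    rows[[sid]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
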