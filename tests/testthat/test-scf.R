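test_that("plate construction scales and centres the hole", {
  circ <- theoretical_set(3)$circle
  geom <- build_plate(circ, hole_fraction = 0.4, plate_w = 10)
  v <- geom$hole$vertices
  expect_equal(polygon_diameter(v), 4, tolerance = 1e-9)
  expect_equal(polygon_centroid(v), c(5, 5), tolerance = 1e-6)
  key <- theoretical_set()$keyhole_w85
  gk <- build_plate(key, 0.4, 10)
  expect_equal(polygon_diameter(gk$hole$vertices), 4, tolerance = 1e-6)
  expect_identical(geom$plate_h / geom$plate_w, 1)
  expect_identical(geom$plate_w / geom$thickness, 10)
})

test_that("meshed plate area equals plate minus shoelace hole area", {
  geom <- build_plate(theoretical_set(3)$keyhole_w50, 0.4, 10)
  m <- mesh_plate(geom, target_edge = 10 / 60)
  mesh_area <- sum(orbitmorph:::element_signed_areas(m$nodes, m$elements))
  expect_equal(mesh_area, 100 - abs(polygon_area(geom$hole$vertices)),
               tolerance = 1e-3)
})

test_that("quasi-homothetic scaling keeps force per bearing area constant", {
  ts <- theoretical_set()
  ref <- build_plate(ts$circle, 0.4, 10)
  expect_equal(scale_loads(ref, ref, 1), 1)
  ratios <- vapply(ts, function(o) {
    g <- build_plate(o, 0.4, 10)
    scale_loads(ref, g, 1) / (bearing_area(g) * g$thickness)
  }, numeric(1))
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-9)
  # a smaller hole leaves more bearing area and receives more force
  small_hole <- build_plate(ts$circle, 0.2, 10)
  f <- scale_loads(ref, small_hole, 1)
  expect_gt(f, 1)
  expect_equal(f, bearing_area(small_hole) / bearing_area(ref))
})

test_that("an unpierced plate has unit stress concentration", {
  comp <- fx_companion()
  s <- stress_concentration(comp$sol, comp$mesh, comp$sol, comp$mesh)
  expect_equal(s$factor, 1, tolerance = 0.05)
})

test_that("the performance table has one row per shape and scenario and records failures", {
  circ <- theoretical_set(3)$circle
  pt <- performance_table(list(circle = circ), target_edge = 10 / 40)
  expect_identical(nrow(pt), 4L)
  expect_true(all(is.na(pt$error)))
  expect_true(all(pt$scf > 0))
  # a shape too large for the plate is recorded, not fatal
  pt2 <- performance_table(list(circle = circ, bad = circ),
                           scenarios = "dv_compression",
                           hole_fraction = 0.4, target_edge = 10 / 40)
  expect_true(all(is.na(pt2$error[pt2$shape_id == "circle"])))
  # a crescent whose centroid sits outside the outline defeats the
  # star-shaped ring mesher for that shape only
  th_out <- seq(0.8, 2 * pi - 0.8, length.out = 40)
  th_in <- rev(th_out)
  crescent <- rbind(cbind(cos(th_out), sin(th_out)),
                    cbind(0.55 * cos(th_in), 0.55 * sin(th_in)))
  cres <- orbit_outline(crescent * 500, taxon = "crescent")
  pt3 <- performance_table(list(ok = circ, crescent = cres),
                           scenarios = "dv_compression",
                           target_edge = 10 / 40)
  expect_true(all(is.na(pt3$error[pt3$shape_id == "ok"])))
  expect_false(anyNA(pt3$error[pt3$shape_id == "crescent"]))
})

test_that("shear scenarios use the companion maximum principal stress", {
  comp <- fx_companion()
  m <- comp$mesh
  sol <- solve_plate(m, fx_material(),
                     make_load_case(m, "anterior_shear", 1), 1)
  ref <- reference_stress(sol, m, "anterior_shear")
  i <- orbitmorph:::node_nearest(m, c(5, 5))
  s <- sol$nodal_stress[i, ]
  mean_s <- (s[["sxx"]] + s[["syy"]]) / 2
  rad <- sqrt(((s[["sxx"]] - s[["syy"]]) / 2)^2 + s[["txy"]]^2)
  expect_equal(ref, max(abs(mean_s + rad), abs(mean_s - rad)))
})
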