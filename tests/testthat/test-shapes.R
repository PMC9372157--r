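test_that("every shape family yields a valid closed simple polygon at the requested size", {
  for (fam in c("circle", "ellipse", "keyhole", "wedge")) {
    o <- make_outline(shape_params(fam, size = 1000))
    expect_true(polygon_is_simple(o$vertices), info = fam)
    expect_gt(polygon_area(o$vertices), 0)
    expect_equal(polygon_diameter(o$vertices), 1000, tolerance = 1e-6)
    expect_gte(nrow(o$vertices), 64)
  }
})

test_that("circle vertices all lie at half the size from the centroid", {
  o <- make_outline(shape_params("circle", size = 1000))
  r <- sqrt(rowSums(sweep(o$vertices, 2, polygon_centroid(o$vertices))^2))
  expect_equal(max(abs(r - 500)), 0, tolerance = 1e-6)
})

test_that("ellipse aspect controls the bounding box ratio", {
  o <- make_outline(shape_params("ellipse", aspect = 2))
  bb <- apply(o$vertices, 2, function(z) diff(range(z)))
  expect_equal(bb[2] / bb[1], 2, tolerance = 1e-9)
})

test_that("keyhole waist matches the brute-force slice-width oracle", {
  k <- make_outline(shape_params("keyhole", waist = 0.6, waist_pos = 0.5,
                                 size = 1000))
  scan <- slice_width_scan(k$vertices)
  expect_equal(scan$ratio, 0.4, tolerance = 0.02 / 0.4)
  expect_identical(scan$n_min, 1L)
})

test_that("keyholes have exactly one interior width minimum across waist depths", {
  for (w in c(0.2, 0.4, 0.6, 0.8)) {
    k <- make_outline(shape_params("keyhole", waist = w))
    scan <- slice_width_scan(k$vertices)
    expect_identical(scan$n_min, 1L, info = paste("waist", w))
    expect_equal(scan$ratio, 1 - w, tolerance = 0.03, info = paste("waist", w))
  }
})

test_that("make_outline is scale-equivariant", {
  p1 <- make_outline(shape_params("keyhole", waist = 0.5, size = 500))
  p2 <- make_outline(shape_params("keyhole", waist = 0.5, size = 1000))
  d1 <- as.matrix(dist(p1$vertices))
  d2 <- as.matrix(dist(p2$vertices))
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
})

test_that("invalid shape parameters are rejected with informative messages", {
  expect_error(shape_params("keyhole", aspect = 0.5), "aspect")
  expect_error(shape_params("circle", waist = 1), "waist")
  expect_error(shape_params("circle", waist_pos = 0), "waist_pos")
  expect_error(shape_params("circle", size = -1), "size")
  expect_error(shape_params("circle", n_vertices = 10), "n_vertices")
})

test_that("the theoretical set has 21 deterministic shapes covering all families", {
  ts1 <- theoretical_set()
  ts2 <- theoretical_set()
  expect_length(ts1, 21)
  fams <- c("circle", "ellipse", "keyhole", "wedge")
  expect_true(all(vapply(fams, function(f)
    any(grepl(f, names(ts1))), logical(1))))
  expect_identical(lapply(ts1, `[[`, "vertices"),
                   lapply(ts2, `[[`, "vertices"))
  ts3 <- theoretical_set(3)
  expect_length(ts3, 3)
  expect_setequal(names(ts3), c("circle", "ellipse_tall", "keyhole_w50"))
  expect_error(theoretical_set(2), ">= 3")
  expect_error(theoretical_set(22), "21")
})

test_that("all 21 theoretical shapes are pairwise distinct in shape space", {
  lms <- landmark_outlines(theoretical_set())
  n <- length(lms)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    expect_gt(procrustes_distance(lms[[i]], lms[[j]]), 1e-3,
              label = paste(names(lms)[i], "vs", names(lms)[j]))
  }
})

test_that("population generation is reproducible and respects the waist bounds", {
  p1 <- generate_population(n = 40, seed = 42)
  p2 <- generate_population(n = 40, seed = 42)
  expect_identical(lapply(p1, `[[`, "vertices"), lapply(p2, `[[`, "vertices"))
  cv <- population_covariates(p1)
  expect_true(all(cv$waist >= 0 & cv$waist < 0.95))
  expect_true(all(vapply(p1, function(o) polygon_is_simple(o$vertices),
                         logical(1))))
  expect_error(generate_population(n = 1), "n must be >= 2")
})

test_that("a null population (no effects, no noise) is a set of identical circles", {
  p <- generate_population(n = 8, seed = 3, beta_size = 0, beta_carn = 0,
                           noise_sd = 0)
  cv <- population_covariates(p)
  expect_true(all(cv$waist == 0))
  shapes <- lapply(p, function(o) {
    s <- standardize_outline(o)
    s$vertices
  })
  for (i in 2:8) expect_equal(shapes[[i]], shapes[[1]], tolerance = 1e-9)
  r <- sqrt(rowSums(shapes[[1]]^2))
  expect_equal(max(abs(r - 500)), 0, tolerance = 1e-6)
})

test_that("skull length drives the realised waist under positive size effects", {
  p <- generate_population(n = 200, seed = 7, beta_size = 2, beta_carn = 1,
                           noise_sd = 0.01)
  cv <- population_covariates(p)
  expect_gte(cor(cv$skull_length_mm, cv$waist, method = "spearman"), 0.8)
})

test_that("outline text files round-trip with covariates", {
  o <- make_outline(shape_params("keyhole", waist = 0.3), taxon = "test_tax",
                    group = "Dinosauria", diet = "carnivore",
                    skull_length = 432.1, time_bin = "Late Jurassic")
  f <- withr::local_tempfile(fileext = ".txt")
  write_outline(o, f)
  o2 <- read_outline(f)
  expect_equal(o2$vertices, o$vertices, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(o2$taxon, "test_tax")
  expect_identical(o2$diet, "carnivore")
  expect_equal(o2$skull_length, 432.1)
})
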