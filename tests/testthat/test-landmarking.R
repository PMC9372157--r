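test_that("standardization scales the largest bounding-box extent to 1000 and centres it", {
  o <- make_outline(shape_params("circle", size = 7))
  o$vertices <- sweep(o$vertices, 2, c(100, -3), `+`)
  s <- standardize_outline(o)
  r <- sqrt(rowSums(s$vertices^2))
  expect_equal(max(abs(r - 500)), 0, tolerance = 1e-6)
  e <- standardize_outline(make_outline(shape_params("ellipse", aspect = 2)))
  bb <- apply(e$vertices, 2, function(z) diff(range(z)))
  expect_equal(bb[2], 1000, tolerance = 1e-6)
  expect_equal(bb[1], 500, tolerance = 1e-6)
  ctr <- colMeans(apply(e$vertices, 2, range))
  expect_equal(max(abs(ctr)), 0, tolerance = 1e-9)
})

test_that("standardization is idempotent", {
  for (fam in c("ellipse", "keyhole", "wedge")) {
    o <- standardize_outline(make_outline(shape_params(fam)))
    o2 <- standardize_outline(o)
    expect_equal(o2$vertices, o$vertices, tolerance = 1e-9)
  }
})

test_that("landmarking places 64 points with the 8 fixed ones on the cross-hair rays", {
  for (fam in c("circle", "ellipse", "keyhole", "wedge")) {
    lm <- place_landmarks(standardize_outline(make_outline(shape_params(fam))))
    expect_identical(nrow(lm$points), 64L)
    expect_identical(lm$fixed_idx, seq(1L, 64L, by = 8L))
    fixed <- lm$points[lm$fixed_idx, ]
    ang <- atan2(fixed[, 2], fixed[, 1]) %% (2 * pi)
    expect_equal(ang, (0:7) * pi / 4, tolerance = 1e-6, info = fam)
  }
})

test_that("a circle is landmarked at uniform radius and 5.625-degree spacing", {
  lm <- place_landmarks(standardize_outline(
    make_outline(shape_params("circle", n_vertices = 512))))
  r <- sqrt(rowSums(lm$points^2))
  expect_equal(r, rep(500, 64), tolerance = 1e-4)
  ang <- atan2(lm$points[, 2], lm$points[, 1]) %% (2 * pi)
  gaps <- diff(c(ang[1], sort(ang))) * 180 / pi
  expect_equal(max(abs(gaps[-1] - 5.625)), 0, tolerance = 0.01 / 5.625)
})

test_that("the 45-degree fixed landmark matches a brute-force ray/ellipse intersection", {
  e <- standardize_outline(make_outline(
    shape_params("ellipse", aspect = 2, n_vertices = 2048)))
  lm <- place_landmarks(e)
  p45 <- lm$points[9, ]  # fixed landmark on the 45-degree ray
  # independent oracle: root of the implicit ellipse equation along the ray
  f <- function(t) (t * cos(pi / 4) / 250)^2 + (t * sin(pi / 4) / 500)^2 - 1
  r_expect <- uniroot(f, c(1, 1000), tol = 1e-12)$root
  expect_equal(sqrt(sum(p45^2)), r_expect, tolerance = 1e-4)
})

test_that("semi-landmarks divide each sector boundary arc into equal lengths", {
  lm <- place_landmarks(standardize_outline(
    make_outline(shape_params("keyhole", waist = 0.5, n_vertices = 1024))))
  seg <- sqrt(rowSums((lm$points[c(2:64, 1), ] - lm$points)^2))
  # within each sector of 8 segments, lengths should be near-equal
  for (k in 1:8) {
    s <- seg[(k - 1) * 8 + 1:8]
    expect_lt(diff(range(s)) / mean(s), 0.05)
  }
})

test_that("mirror-symmetric outlines get mirror-symmetric landmarks", {
  lm <- place_landmarks(standardize_outline(
    make_outline(shape_params("keyhole", waist = 0.4))))
  pts <- lm$points
  # reflect about the vertical axis; landmark k at angle a maps to the
  # landmark at angle pi - a: index mapping under the ccw-from-0 ordering
  reflected <- cbind(-pts[, 1], pts[, 2])
  remap <- c(33:1, 64:34)  # angle a_i -> pi - a_i
  expect_equal(reflected[remap, ], pts, tolerance = 1e-6)
})

test_that("landmarks are invariant to vertex density and starting vertex", {
  base <- make_outline(shape_params("keyhole", waist = 0.5,
                                    n_vertices = 128))
  lm1 <- place_landmarks(standardize_outline(base))
  dense <- base
  dense$vertices <- resample_polygon(base$vertices, 256)
  lm2 <- place_landmarks(standardize_outline(dense))
  expect_lt(max(abs(lm1$points - lm2$points)), 0.001 * 1000)
  shifted <- base
  shifted$vertices <- base$vertices[c(40:128, 1:39), ]
  lm3 <- place_landmarks(standardize_outline(shifted))
  expect_lt(max(abs(lm1$points - lm3$points)), 1e-6 * 1000)
})

test_that("unstandardized or degenerate outlines are rejected", {
  o <- make_outline(shape_params("circle", size = 7))
  expect_error(place_landmarks(o), "standardize")
})

test_that("TPS files round-trip coordinates and ids", {
  lms <- fx_landmarks_small()[1:5]
  f <- withr::local_tempfile(fileext = ".tps")
  write_tps(lms, f)
  back <- read_tps(f)
  expect_length(back, 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$points, lms[[i]]$points, tolerance = 1e-6)
    expect_identical(back[[i]]$specimen_id, lms[[i]]$specimen_id)
  }
})

test_that("TPS SCALE records multiply coordinates", {
  f <- withr::local_tempfile(fileext = ".tps")
  pts <- sprintf("%d %d", rep(10L, 64), rep(10L, 64))
  writeLines(c("LM=64", pts, "ID=spec1", "SCALE=0.5"), f)
  cfg <- read_tps(f)[[1]]
  expect_equal(unname(cfg$points[1, ]), c(5, 5))
  expect_identical(cfg$specimen_id, "spec1")
})

test_that("TPS parse errors report the offending line", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=64", sprintf("%d %d", 1:10, 1:10), "ID=bad"), f)
  expect_error(read_tps(f), "line")
})
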