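test_that("a population of identical shapes has zero total variance", {
  lm <- fx_landmarks_small()[[1]]$points
  m <- morphospace_pca(gpa(list(lm, lm, lm, lm)))
  expect_true(all(m$variance_fraction == 0))
  expect_true(all(m$scores == 0))
  expect_identical(m$n_effective, 0L)
})

test_that("a one-degree-of-freedom shape family loads entirely on PC1", {
  # linear interpolation between two configurations, with the difference
  # vector purged of translation/scale/rotation components so that a
  # non-scaling superimposition leaves the family exactly collinear
  lms <- landmark_outlines(theoretical_set(3))
  a <- lms$circle$points
  a <- sweep(a, 2, colMeans(a)); a <- a / sqrt(sum(a^2))
  b <- lms$keyhole_w50$points
  b <- sweep(b, 2, colMeans(b)); b <- b / sqrt(sum(b^2))
  d <- b - a
  d <- d - a * sum(a * d) / sum(a * a)             # remove size direction
  rot_dir <- cbind(-a[, 2], a[, 1])                 # infinitesimal rotation
  d <- d - rot_dir * sum(rot_dir * d) / sum(rot_dir^2)
  fam <- lapply(seq(0, 1, length.out = 9), function(t) a + t * d)
  m <- morphospace_pca(gpa(fam, scale = FALSE))
  expect_equal(m$variance_fraction[1], 1, tolerance = 1e-6)
  # with standard scaling GPA the family is still overwhelmingly 1-D
  ms <- morphospace_pca(gpa(fam, scale = TRUE))
  expect_gt(ms$variance_fraction[1], 0.99)
})

test_that("eigenvalues match an independent covariance eigendecomposition", {
  g <- gpa(fx_landmarks_small()[1:10])
  m <- morphospace_pca(g)
  # oracle: flatten the aligned array directly and eigendecompose its
  # covariance matrix
  x <- t(sapply(1:10, function(i) as.vector(g$aligned[, , i])))
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  total <- sum(ev)
  r <- length(m$variance_fraction)
  expect_equal(m$variance_fraction, pmax(ev[seq_len(r)], 0) / total,
               tolerance = 1e-8)
  expect_true(all(diff(m$variance_fraction) <= 1e-12))
})

test_that("eigenvectors are orthonormal and scores are centred", {
  m <- fx_model_small()
  gram <- crossprod(m$eigenvectors)
  expect_equal(gram, diag(ncol(m$eigenvectors)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(m$scores))), 1e-10)
})

test_that("the PC sign convention makes repeated runs bitwise identical", {
  lms <- fx_landmarks_small()[1:15]
  m1 <- morphospace_pca(gpa(lms))
  m2 <- morphospace_pca(gpa(lms))
  expect_identical(m1$scores, m2$scores)
  expect_identical(m1$eigenvectors, m2$eigenvectors)
})

test_that("pc_distance is the PC1-3 Euclidean norm with zero-padding", {
  sc <- rbind(c(0, 0, 0), c(0.3, 0.4, 0), c(1, 2, 2))
  d <- pc_distance(sc)
  expect_equal(d$d_pc123, c(0, 0.5, 3))
  # rank-deficient: 2 specimens give a single PC
  lms <- fx_landmarks_small()[1:2]
  m <- morphospace_pca(gpa(lms))
  d2 <- pc_distance(m)
  expect_equal(d2$d_pc123, abs(m$scores[, 1]), ignore_attr = TRUE)
})

test_that("the specimen with the deepest waist is farthest from the origin", {
  m <- fx_model_small()
  cv <- population_covariates(fx_population_small())
  d <- pc_distance(m)
  expect_equal(cv$waist[which.max(d$d_pc123)], max(cv$waist))
})

test_that("projection reproduces training scores and is rotation-invariant", {
  m <- fx_model_small()
  lms <- fx_landmarks_small()
  expect_equal(project_config(m, lms[[7]]),
               unname(m$scores[7, ]), tolerance = 1e-6)
  rot <- lms[[7]]$points %*% t(rotmat(63)) * 1.7
  expect_equal(project_config(m, rot), unname(m$scores[7, ]),
               tolerance = 1e-6)
  pr <- project_config(m, m$consensus)
  expect_lt(max(abs(pr)), 0.05 * max(abs(m$scores)))
  expect_error(project_config(m, matrix(0, 10, 2)), "mismatch")
})

test_that("PC1 tracks the generating waist parameter", {
  m <- fx_model_small()
  cv <- population_covariates(fx_population_small())
  expect_gte(abs(cor(m$scores[, 1], cv$waist)), 0.9)
})
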