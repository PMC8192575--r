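test_that("capsule rasterization matches exhaustive voxel-center distance check", {
  for (seed in 1:5) {
    set.seed(seed)
    shape <- sample(8:32, 3, replace = TRUE)
    spacing <- sample(c(0.5, 0.7, 1.0), 3, replace = TRUE)
    g <- grid_spec(shape, spacing)
    ext <- (shape - 1) * spacing
    segs <- list(list(start = runif(3, 0.2, 0.4) * ext,
                      end = runif(3, 0.6, 0.8) * ext,
                      radius = runif(1, max(spacing) * 1.05,
                                     max(spacing) * 2.5)))
    ph <- make_tube_phantom(phantom_spec(segs, g, seed = seed))
    # oracle: loop over every voxel center, point-to-segment distance
    a <- segs[[1]]$start; b <- segs[[1]]$end; r <- segs[[1]]$radius
    expected <- array(0L, shape)
    for (k in 1:shape[3]) for (j in 1:shape[2]) for (i in 1:shape[1]) {
      p <- (c(i, j, k) - 1) * spacing
      ab <- b - a
      t <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
      d <- sqrt(sum((p - a - t * ab)^2))
      expected[i, j, k] <- as.integer(d <= r)
    }
    expect_identical(ph$mask$data, expected)
  }
})

test_that("axis-aligned radius-3 tube has the 29-voxel discrete disc cross-section", {
  ph <- test_tube(radius = 3, spacing = 1)
  mid <- round(dim(ph$mask$data)[3] / 2)
  expect_equal(sum(ph$mask$data[, , mid]), 29)
})

test_that("phantom generation is deterministic and noise-free when asked", {
  g <- grid_spec(c(20, 20, 20), 1)
  segs <- list(list(start = c(9, 9, 2), end = c(9, 9, 17), radius = 2.5))
  p1 <- make_tube_phantom(phantom_spec(segs, g, noise_voxel_count = 5L,
                                       seed = 42L))
  p2 <- make_tube_phantom(phantom_spec(segs, g, noise_voxel_count = 5L,
                                       seed = 42L))
  expect_identical(p1$mask$data, p2$mask$data)
  expect_identical(p1$noise_voxels, p2$noise_voxels)

  p0 <- make_tube_phantom(phantom_spec(segs, g, noise_voxel_count = 0L,
                                       seed = 42L))
  # no-noise mask is the exact capsule; the noisy mask differs only by the
  # isolated voxels
  expect_equal(sum(p1$mask$data) - sum(p0$mask$data), 5)
  expect_equal(nrow(p1$noise_voxels), 5)
})

test_that("noise voxels are isolated, low-probability, and exactly removed by refinement", {
  ph <- test_tube(radius = 2.5, spacing = 1, noise = 8L, seed = 3L)
  p0 <- test_tube(radius = 2.5, spacing = 1, noise = 0L, seed = 3L)
  # atlas below 1% at every noise voxel
  for (r in seq_len(nrow(ph$noise_voxels))) {
    v <- ph$noise_voxels[r, ]
    expect_lt(ph$prob_atlas$data[v[1], v[2], v[3]], 0.01)
  }
  refined <- refine_segmentation(ph$mask, ph$prob_atlas)
  expect_identical(refined$data, p0$mask$data)
  # isolation: each noise voxel is its own 26-component
  expect_equal(count_components26(ph$mask$data),
               count_components26(p0$mask$data) + nrow(ph$noise_voxels))
})

test_that("ground-truth centerline voxels are foreground, atlas is high on the vessel", {
  for (seed in 1:5) {
    ph <- random_tube_phantom(seed)
    for (cl in ph$true_centerline)
      expect_true(all(ph$mask$data[cl] == 1L))
  }
  ph <- test_tube(radius = 2, spacing = 1)
  expect_true(all(ph$prob_atlas$data[ph$mask$data == 1L] >= 0.5))
})

test_that("phantom specs reject out-of-grid segments and under-resolved radii", {
  g <- grid_spec(c(10, 10, 10), 1)
  expect_error(phantom_spec(list(list(start = c(1, 1, 1), end = c(30, 1, 1),
                                      radius = 2)), g),
               "outside the grid")
  expect_error(phantom_spec(list(list(start = c(2, 2, 2), end = c(8, 8, 8),
                                      radius = 0.4)), g),
               "under-resolved")
})

test_that("cohort: noiseless responses are an exact linear model in the predictors", {
  B <- matrix(0, 9, 24)
  B[3, ] <- 0.5   # age effect on everything
  B[1, 7] <- -0.2
  spec <- cohort_sim_spec(n_subjects = 120, effect_matrix = B, noise_sd = 0,
                          fetal_pca_fraction = 0, seed = 11)
  d <- make_cohort(spec)
  X <- scale(as.matrix(d[, predictor_names()]))
  for (j in c(1, 7, 20)) {
    y <- d[[measurement_names("all")[j]]]
    bhat <- coef(lm(y ~ X))[-1]
    expect_equal(unname(bhat), B[, j], tolerance = 1e-9)
  }
})

test_that("cohort generation is deterministic and codes sex/drinks as documented", {
  s <- cohort_sim_spec(n_subjects = 200, seed = 5)
  d1 <- make_cohort(s)
  d2 <- make_cohort(s)
  expect_identical(d1, d2)
  expect_true(all(d1$sex %in% c(1, 2)))
  expect_true(all(d1$drinks %in% 0:5))
  expect_true(all(d1$smoking_years >= 0))
  expect_named(d1, c("subject_id", predictor_names(), "fetal_pca",
                     measurement_names("all")))
})

test_that("variant carrier count stays within the binomial 99% interval", {
  d <- make_cohort(cohort_sim_spec(n_subjects = 1600,
                                   fetal_pca_fraction = 0.125, seed = 21))
  n_var <- sum(d$fetal_pca)
  bounds <- qbinom(c(0.005, 0.995), 1600, 0.125)
  expect_gte(n_var, bounds[1])
  expect_lte(n_var, bounds[2])
})

test_that("identity predictor correlation yields near-zero sample correlations", {
  d <- make_cohort(cohort_sim_spec(n_subjects = 5000,
                                   predictor_corr = diag(9), seed = 31))
  cont <- c("icv_cm3", "age", "bmi", "whr", "sbp", "heart_rate")
  R <- cor(as.matrix(d[, cont]))
  expect_lt(max(abs(R[upper.tri(R)])), 0.1)
})

test_that("non-positive-definite correlation is rejected naming the eigenvalue", {
  R <- diag(9)
  R[1, 2] <- R[2, 1] <- 1.0 # rank-deficient
  expect_error(cohort_sim_spec(100, predictor_corr = R),
               "positive definite.*eigenvalue|eigenvalue",)
})
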