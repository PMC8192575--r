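test_that("atlas refinement follows the strictly-below rule and is anti-extensive", {
  g <- grid_spec(c(4, 4, 4), 1)
  mask <- array(1L, c(4, 4, 4))
  atlas <- array(0.5, c(4, 4, 4))
  atlas[1, 1, 1] <- 0.005  # below 1%: removed
  atlas[2, 1, 1] <- 0.01   # exactly 1%: kept
  atlas[3, 1, 1] <- 0.0099
  mv <- binary_volume(mask, g)
  av <- probability_volume(atlas, g)
  out <- refine_segmentation(mv, av)
  expect_equal(out$data[1, 1, 1], 0L)
  expect_equal(out$data[2, 1, 1], 1L)
  expect_equal(out$data[3, 1, 1], 0L)
  expect_true(all(out$data <= mv$data))
  # idempotent
  expect_identical(refine_segmentation(out, av)$data, out$data)
  # identity atlas
  ones <- probability_volume(array(1, c(4, 4, 4)), g)
  expect_identical(refine_segmentation(mv, ones)$data, mv$data)
  # grid mismatch names both geometries
  g2 <- grid_spec(c(4, 4, 4), 0.7)
  expect_error(refine_segmentation(mv, probability_volume(atlas, g2)),
               "not on the same grid")
})

test_that("distance transform handles the forced small geometries", {
  g <- grid_spec(c(5, 5, 5), 1)
  one <- array(0L, c(5, 5, 5)); one[3, 3, 3] <- 1L
  d <- distance_transform(binary_volume(one, g))
  expect_equal(d[3, 3, 3], 1.0)
  expect_true(all(d[one == 0L] == 0))

  block <- array(0L, c(5, 5, 5)); block[2:4, 2:4, 2:4] <- 1L
  d <- distance_transform(binary_volume(block, g))
  expect_equal(d[3, 3, 3], 2.0)

  expect_error(distance_transform(binary_volume(array(1L, c(3, 3, 3)), g <- grid_spec(c(3, 3, 3), 1))),
               "all-foreground")
})

test_that("distance transform equals the brute-force oracle on random anisotropic masks", {
  for (seed in 1:25) {
    m <- random_mask(seed, max_dim = 12,
                     spacing = sample(c(0.5, 0.7, 1.0), 3, replace = TRUE))
    expect_equal(distance_transform(m), brute_edt(m), tolerance = 1e-12)
  }
})

test_that("already-thin structures survive thinning unchanged", {
  g <- grid_spec(c(12, 12, 12), 1)
  arr <- array(0L, c(12, 12, 12))
  for (t in 0:9) arr[2 + t, 6, 6] <- 1L  # straight 1-voxel path
  cl <- skeletonize3d(binary_volume(arr, g))
  expect_identical(centerline_to_array(cl), arr)
})

test_that("cylinder skeleton is one component hugging the axis; two tubes give two", {
  ph <- test_tube(radius = 3, spacing = 1, length_mm = 20)
  cl <- skeletonize3d(ph$mask)
  sk <- centerline_to_array(cl)
  expect_true(all(ph$mask$data[cl$voxels] == 1L)) # subset of mask
  expect_equal(count_components26(sk), 1)
  # every skeleton voxel within 1 voxel of the true axis (caps included)
  axis_ij <- ph$true_centerline[[1]][1, 1:2]
  off <- sweep(cl$voxels[, 1:2, drop = FALSE], 2, axis_ij)
  expect_true(all(sqrt(rowSums(off^2)) <= sqrt(2) + 1e-9))

  g <- grid_spec(c(24, 24, 24), 1)
  segs <- list(list(start = c(6, 6, 2), end = c(6, 6, 21), radius = 2),
               list(start = c(17, 17, 2), end = c(17, 17, 21), radius = 2))
  ph2 <- make_tube_phantom(phantom_spec(segs, g))
  expect_equal(count_components26(centerline_to_array(skeletonize3d(ph2$mask))), 2)
})

test_that("thinning preserves component count and is idempotent on random phantoms", {
  for (seed in 1:10) {
    ph <- random_tube_phantom(seed)
    cl <- skeletonize3d(ph$mask)
    sk <- centerline_to_array(cl)
    expect_equal(count_components26(sk), count_components26(ph$mask$data))
    expect_true(all(ph$mask$data[cl$voxels] == 1L))
    # fixed point
    expect_identical(centerline_to_array(skeletonize3d(binary_volume(sk, ph$mask$grid))), sk)
  }
  # empty mask is fine
  empty <- binary_volume(array(0L, c(4, 4, 4)), grid_spec(c(4, 4, 4), 1))
  expect_equal(length(skeletonize3d(empty)), 0)
})

test_that("centerline radii recover tube radius within the voxel-center tolerance", {
  interior <- function(cl, frac = 0.3) {
    zr <- range(cl$voxels[, 3])
    span <- diff(zr)
    keep <- cl$voxels[, 3] >= zr[1] + frac * span &
            cl$voxels[, 3] <= zr[2] - frac * span
    cl$radius_mm[keep]
  }
  ph <- test_tube(radius = 3, spacing = 1, length_mm = 24)
  cl <- centerline_radii(skeletonize3d(ph$mask), distance_transform(ph$mask))
  m1 <- mean(interior(cl))
  expect_gte(m1, 2.5); expect_lte(m1, 3.5)

  ph5 <- test_tube(radius = 3, spacing = 0.5, length_mm = 24)
  cl5 <- centerline_radii(skeletonize3d(ph5$mask), distance_transform(ph5$mask))
  m5 <- mean(interior(cl5))
  expect_gte(m5, 2.75); expect_lte(m5, 3.25)
  expect_lte(abs(m5 - 3), abs(m1 - 3) + 1e-9) # finer grid at least as good

  # one-voxel-wide line: radius is one spacing unit
  g <- grid_spec(c(10, 10, 10), 1)
  arr <- array(0L, c(10, 10, 10)); arr[3:8, 5, 5] <- 1L
  lv <- binary_volume(arr, g)
  cll <- centerline_radii(skeletonize3d(lv), distance_transform(lv))
  expect_true(all(cll$radius_mm == 1))

  # inconsistent inputs: distance map of a different (empty) mask
  other <- distance_transform(binary_volume(array(0L, c(10, 10, 10)), g))
  expect_error(centerline_radii(skeletonize3d(lv), other), "zero distance")
})

test_that("territory density is the plain voxel-count ratio", {
  g <- grid_spec(c(10, 10, 10), 1)
  ter <- array(1L, c(10, 10, 10))
  terv <- label_volume(ter, g, c(all = 1L))
  arr <- array(0L, c(10, 10, 10)); arr[1:10, 1, 1] <- 1L
  expect_equal(territory_density(binary_volume(arr, g), terv, "all"), 1.0)
  expect_equal(territory_density(binary_volume(array(0L, c(10, 10, 10)), g),
                                 terv, "all"), 0)
  expect_error(territory_density(binary_volume(arr, g),
                                 label_volume(ter, g, c(all = 1L, gone = 2L)),
                                 "gone"), "empty")
  # phantom with hand-counted capsule voxels per territory
  ph <- test_tube(radius = 2, spacing = 1)
  for (lab in names(ph$territories$label_names)) {
    id <- ph$territories$label_names[[lab]]
    sel <- ph$territories$data == id
    expect_equal(territory_density(ph$mask, ph$territories, lab),
                 100 * sum(ph$mask$data[sel]) / sum(sel))
  }
})

test_that("regional mean radius averages centerline voxels only, NA when region empty of them", {
  g <- grid_spec(c(12, 12, 12), 1)
  ter <- label_volume(array(1L, c(12, 12, 12)), g, c(all = 1L))
  vox <- rbind(c(2, 2, 2))
  cl <- centerline_set(vox, g, radius_mm = 2.0)
  expect_equal(territory_mean_radius(cl, ter, "all"), 2.0)

  # two tubes radii 2 and 4 with equal voxel counts
  vox2 <- rbind(cbind(3:7, 3, 3), cbind(3:7, 9, 9))
  cl2 <- centerline_set(vox2, g, radius_mm = c(rep(2, 5), rep(4, 5)))
  expect_equal(territory_mean_radius(cl2, ter, "all"), 3.0)

  half <- array(0L, c(12, 12, 12)); half[, , 12] <- 1L
  offv <- label_volume(half, g, c(top = 1L))
  expect_message(r <- territory_mean_radius(cl2, offv, "top"), "recording NA")
  expect_true(is.na(r))
})

test_that("artery mask means sit between the radii of a stepped vessel", {
  g <- grid_spec(c(16, 16, 30), 1)
  segs <- list(list(start = c(7, 7, 2), end = c(7, 7, 14), radius = 2),
               list(start = c(7, 7, 14), end = c(7, 7, 27), radius = 1.05))
  ph <- make_tube_phantom(phantom_spec(segs, g))
  cl <- centerline_radii(skeletonize3d(ph$mask), distance_transform(ph$mask))
  # mask over the step
  step <- array(0L, dim = g$shape); step[, , 12:17] <- 1L
  stepv <- label_volume(step, g, c(step = 1L))
  m <- artery_mean_radius(cl, stepv, "step")
  expect_gte(m, 1); expect_lte(m, 2 + 0.5)
  # mask over the thin half only
  thin <- array(0L, dim = g$shape); thin[, , 19:25] <- 1L
  mt <- artery_mean_radius(cl, label_volume(thin, g, c(thin = 1L)), "thin")
  expect_lt(abs(mt - 1.05), 0.5 + 1e-9)
})

test_that("intracranial volume is count times voxel volume", {
  g <- grid_spec(c(10, 10, 10), 1)
  arr <- array(0L, c(10, 10, 10)); arr[seq_len(1000)] <- 1L
  expect_equal(intracranial_volume(binary_volume(arr, g)), 1.0)
  g7 <- grid_spec(c(10, 10, 10), 0.7)
  expect_equal(intracranial_volume(binary_volume(arr, g7)), 0.343)
  expect_error(intracranial_volume(binary_volume(array(0L, c(10, 10, 10)), g)),
               "empty")
  # cohort-scale arithmetic: 1,402,440 voxels at 1 mm = 1402.44 cm^3
  gb <- grid_spec(c(120, 120, 120), 1)
  big <- array(0L, c(120, 120, 120)); big[seq_len(1402440)] <- 1L
  expect_equal(intracranial_volume(binary_volume(big, gb)), 1402.44)
})

test_that("extract_measurements populates all fields near truth and flags annihilation", {
  ph <- test_tube(radius = 2.5, spacing = 1, shape = c(21, 21, 24), noise = 3L)
  m <- extract_measurements(ph$mask, ph$prob_atlas, ph$territories,
                            ph$artery_masks, ph$icv_mask)
  expect_false(m$qc_empty_refined)
  expect_true(all(is.finite(unlist(m[measurement_names("density")]))))
  tr <- unlist(m[measurement_names("territory_radius")])
  ar <- unlist(m[measurement_names("artery_radius")])
  # regions crossed by the tube: radii within half a voxel + half spacing
  expect_true(all(abs(tr[!is.na(tr)] - 2.5) <= 1.0))
  expect_true(all(abs(ar[!is.na(ar)] - 2.5) <= 1.0))
  expect_gt(m$icv_cm3, 0)
  # determinism
  m2 <- extract_measurements(ph$mask, ph$prob_atlas, ph$territories,
                             ph$artery_masks, ph$icv_mask)
  expect_identical(m, m2)
  # atlas that annihilates the mask
  low <- probability_volume(array(0.001, dim = ph$mask$grid$shape),
                            ph$mask$grid)
  m0 <- extract_measurements(ph$mask, low, ph$territories,
                             ph$artery_masks, ph$icv_mask)
  expect_true(m0$qc_empty_refined)
  expect_true(all(is.na(unlist(m0[measurement_names("all")]))))
})

test_that("sub-territory labels are unioned before measurement", {
  ph <- test_tube(radius = 2, spacing = 1)
  g <- ph$mask$grid
  # split the ACA_L territory of the phantom into proximal/distal halves
  ter <- ph$territories
  dat <- ter$data
  sel <- dat == ter$label_names[["territory_ACA_L"]]
  k_split <- round(g$shape[3] / 6)
  prox <- sel & slice.index(dat, 3) <= k_split
  dat2 <- dat
  dat2[] <- 0L
  dat2[prox] <- 1L
  dat2[sel & !prox] <- 2L
  dat2[!sel] <- dat[!sel] + 2L
  nm <- c(territory_ACA_L_proximal = 1L, territory_ACA_L_distal = 2L,
          setNames(ter$label_names[-1] + 2L, names(ter$label_names)[-1]))
  split_ter <- label_volume(dat2, g, nm)
  m_split <- extract_measurements(ph$mask, ph$prob_atlas, split_ter,
                                  ph$artery_masks, ph$icv_mask)
  m_plain <- extract_measurements(ph$mask, ph$prob_atlas, ph$territories,
                                  ph$artery_masks, ph$icv_mask)
  expect_equal(m_split$density_ACA_L, m_plain$density_ACA_L)
  expect_equal(m_split$tradius_ACA_L, m_plain$tradius_ACA_L)
})
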