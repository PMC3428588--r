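test_that("sphere ROI volume approaches the analytic ball volume", {
  analytic <- 4 / 3 * pi * 12^3
  v2 <- mask_volume(roi_sphere(c(0, 0, 0), 12, grid_spec(2)))
  expect_lt(abs(v2 - analytic) / analytic, 0.03)
  g1 <- grid_spec(1, box = rbind(c(-20, -20, -20), c(20, 20, 20)))
  v1 <- mask_volume(roi_sphere(c(0, 0, 0), 12, g1))
  expect_lt(abs(v1 - analytic) / analytic, 0.02)
  # finer grid approximates better
  expect_lt(abs(v1 - analytic), abs(v2 - analytic))
})

test_that("sphere membership is exact: every set voxel center is within radius", {
  g <- tiny_grid(10, spacing = 2)
  ctr <- c(4, 4, 4)
  m <- roi_sphere(ctr, 5, g)
  set <- which(m$vox, arr.ind = TRUE)
  cc <- voxel_to_coord(g, set)
  d <- sqrt(rowSums(sweep(cc, 2, ctr)^2))
  expect_true(all(d <= 5 + 1e-12))
  unset <- which(!m$vox, arr.ind = TRUE)
  cu <- voxel_to_coord(g, unset)
  expect_true(all(sqrt(rowSums(sweep(cu, 2, ctr)^2)) > 5))
})

test_that("dilation of a single voxel gives 27 then 125 voxels", {
  g <- tiny_grid(9, spacing = 1)
  m <- cube_mask(g, 5, 5, 5)
  expect_equal(sum(dilate(m, 0L)$vox), 1L)
  expect_equal(sum(dilate(m, 1L)$vox), 27L)
  expect_equal(sum(dilate(m, 2L)$vox), 125L)
})

test_that("dilation matches a brute-force 26-neighborhood oracle", {
  set.seed(21)
  g <- tiny_grid(6, spacing = 1)
  vox <- array(runif(prod(g$shape)) < 0.2, dim = g$shape)
  m <- roi_mask(g, vox)
  out <- dilate(m, 1L)$vox
  oracle <- array(FALSE, dim = g$shape)
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    ni <- max(1, i - 1):min(6, i + 1)
    nj <- max(1, j - 1):min(6, j + 1)
    nk <- max(1, k - 1):min(6, k + 1)
    oracle[i, j, k] <- any(vox[ni, nj, nk])
  }
  expect_identical(out, oracle)
  # dilation only ever adds voxels
  expect_true(all(out[vox]))
})

test_that("half-space clips keep the correct voxel centers", {
  g <- tiny_grid(8, spacing = 2)   # centers -2, 0, 2, ..., 12
  m <- full_mask(g)
  post <- clip_halfspace(m, 2L, "below", 4)
  ant <- clip_halfspace(m, 2L, "above", 4)
  expect_true(all(grid_axis(g, 2)[apply(post$vox, 2, any)] <= 4))
  expect_true(all(grid_axis(g, 2)[apply(ant$vox, 2, any)] >= 4))
  # closed on both sides: the cutoff plane (a voxel-center plane) is in both
  expect_equal(sum(post$vox) + sum(ant$vox), sum(m$vox) + 8L * 8L)
})

test_that("2mm->1mm up-conversion preserves volume exactly and round-trips", {
  m2 <- roi_sphere(c(0, 0, 0), 12, grid_spec(2))
  m1 <- resample_mask(m2, 1)
  expect_equal(mask_volume(m1), mask_volume(m2))
  back <- resample_mask(m1, 2)
  expect_identical(back$vox, m2$vox)
})

test_that("1mm->2mm down-conversion follows the majority rule with ties set", {
  g1 <- grid_spec(1, box = rbind(c(0, 0, 0), c(7, 7, 7)))
  vox <- array(FALSE, dim = g1$shape)
  vox[1:2, 1:2, 1]    <- TRUE   # 4 of 8 children: tie -> set
  vox[3, 3, 3]        <- TRUE   # 1 of 8: majority says unset
  vox[5:6, 5:6, 5:6]  <- TRUE   # 8 of 8: set
  m1 <- roi_mask(g1, vox)
  maj <- resample_mask(m1, 2)
  expect_true(maj$vox[1, 1, 1])
  expect_false(maj$vox[2, 2, 2])
  expect_true(maj$vox[3, 3, 3])
  any_rule <- resample_mask(m1, 2, rule = "any")
  expect_true(any_rule$vox[2, 2, 2])
  # "any" is always a superset of "majority"
  expect_true(all(any_rule$vox[maj$vox]))
})

test_that("down-then-up changes volume by at most a voxel layer for a sphere", {
  g1 <- grid_spec(1, box = rbind(c(-20, -20, -20), c(20, 20, 20)))
  m1 <- roi_sphere(c(0, 0, 0), 12, g1)
  rt <- resample_mask(resample_mask(m1, 2), 1)
  # agreement everywhere except near the surface
  frac_diff <- sum(xor(rt$vox, m1$vox)) / sum(m1$vox)
  expect_lt(frac_diff, 0.25)
  expect_equal(mask_volume(rt), mask_volume(m1), tolerance = 0.1)
})

test_that("statistical-map thresholding is closed and tolerates non-finite values", {
  g <- tiny_grid(4, spacing = 1)
  map <- array(0, dim = g$shape)
  map[1, 1, 1] <- 2.5
  map[2, 1, 1] <- 2.4999
  map[3, 1, 1] <- 9
  map[4, 1, 1] <- NaN
  expect_warning(m <- roi_from_statmap(map, 2.5, g), "non-finite")
  expect_true(m$vox[1, 1, 1])     # exactly at threshold: included
  expect_false(m$vox[2, 1, 1])
  expect_true(m$vox[3, 1, 1])
  expect_false(m$vox[4, 1, 1])    # NaN treated as below threshold
  expect_equal(sum(m$vox), 2L)
})

test_that("atlas label selection picks exactly the requested labels", {
  g <- tiny_grid(4, spacing = 1)
  atlas <- array(0L, dim = g$shape)
  atlas[1:2, , ] <- 7L
  atlas[3, , ] <- 8L
  m <- roi_from_labels(atlas, c(7L, 8L), g)
  expect_equal(sum(m$vox), 3L * 16L)
  expect_warning(empty <- roi_from_labels(atlas, 99L, g), "empty")
  expect_equal(sum(empty$vox), 0L)
})

test_that("masks round-trip through NIfTI on disk", {
  m <- roi_sphere(c(0, 0, 0), 6, tiny_grid(12, spacing = 2))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask_nifti(m, path)
  back <- read_mask_nifti(path)
  expect_true(grid_equal(back$grid, m$grid))
  expect_identical(back$vox, m$vox)
})
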