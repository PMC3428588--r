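test_that("coordinates map to the nearest voxel center, ties away from zero", {
  g <- grid_spec(2)
  expect_equal(unname(coord_to_voxel(g, g$origin)[1, ]), c(1L, 1L, 1L))
  # one mm into the first voxel still belongs to it
  expect_equal(unname(coord_to_voxel(g, g$origin + c(1, 0, 0))[1, ]),
               c(1L, 1L, 1L))
  # the stereotaxic origin sits exactly on a voxel center
  o <- coord_to_voxel(g, c(0, 0, 0))
  expect_equal(unname(voxel_to_coord(g, o)[1, ]), c(0, 0, 0))
  # half-spacing ties round away from zero, symmetrically in x
  vr <- voxel_to_coord(g, coord_to_voxel(g, c(1, 0, 0)))
  vl <- voxel_to_coord(g, coord_to_voxel(g, c(-1, 0, 0)))
  expect_equal(unname(vr[1, 1]), 2)
  expect_equal(unname(vl[1, 1]), -2)
  # out-of-box coordinates give NA rows
  expect_true(all(is.na(coord_to_voxel(g, c(500, 0, 0)))))
  # round trip over random in-box points lands within spacing/2 per axis
  set.seed(3)
  pts <- cbind(runif(100, -89, 89), runif(100, -125, 89),
               runif(100, -71, 107))
  back <- voxel_to_coord(g, coord_to_voxel(g, pts))
  expect_true(all(abs(back - pts) <= g$spacing / 2 + 1e-12))
})

test_that("count images tally foci per voxel and report dropped foci", {
  g <- tiny_grid(6, spacing = 2)
  coords <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(2, 2, 2), c(999, 0, 0))
  expect_warning(img <- build_count_image(coords, g), "dropped 1")
  expect_equal(img$n, 3L)
  expect_equal(img$dropped, 1L)
  expect_equal(sum(img$counts), 3L)
  # the two near-origin foci share a voxel
  expect_true(2L %in% img$counts)
})

test_that("normalized channels sum to one; empty channels warn and are zero", {
  g <- tiny_grid(6, spacing = 2)
  img <- build_count_image(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 0, 0)), g)
  ch <- normalize_to_pdf(img)
  expect_equal(sum(ch$val), 1, tolerance = 1e-12)
  expect_equal(ch$n_foci, 3L)
  empty <- build_count_image(matrix(numeric(), 0, 3), g)
  expect_warning(ch0 <- normalize_to_pdf(empty), "no in-grid foci")
  expect_equal(ch0$n_foci, 0L)
  expect_length(ch0$val, 0L)
})

test_that("the assembled 4-D PDF has 51 unit-sum or empty channels", {
  g <- tiny_grid(8, spacing = 2)
  tab <- coords_table(rbind(c(0, 0, 0), c(2, 2, 2), c(4, 0, 2),
                            c(0, 0, 0)),
                      subdomain_id = c(14L, 14L, 27L, 27L))
  pdf <- assemble_pdf4d(tab, g)
  expect_s3_class(pdf, "behavior_pdf4d")
  expect_length(pdf$channels, 51L)
  expect_equal(pdf$n_foci[14], 2L)
  expect_equal(pdf$n_foci[27], 2L)
  expect_equal(sum(pdf$n_foci), 4L)
  sums <- vapply(pdf$channels, function(ch) sum(ch$val), numeric(1))
  expect_equal(sums[pdf$n_foci > 0], rep(1, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(sums[pdf$n_foci == 0] == 0))
  # channel order follows the taxonomy: channel b is sub-domain id b
  expect_identical(pdf$taxonomy$id, 1:51)
})

test_that("an MNI-tagged table triggers a warning at assembly", {
  g <- tiny_grid(6, spacing = 2)
  tab <- coords_table(c(0, 0, 0), space = "MNI")
  expect_warning(assemble_pdf4d(tab, g), "MNI")
})

test_that("the 4-D PDF round-trips through compressed NIfTI plus sidecar", {
  g <- grid_spec(2, box = rbind(c(-10, -10, -10), c(10, 10, 10)))
  set.seed(5)
  tab <- coords_table(matrix(runif(90, -9, 9), ncol = 3),
                      subdomain_id = rep(c(1L, 14L, 51L), each = 10))
  pdf <- assemble_pdf4d(tab, g)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_pdf4d(pdf, path)
  # gzip-compressed on disk
  magic <- readBin(path, "raw", 2L)
  expect_identical(magic, as.raw(c(0x1f, 0x8b)))
  # 4th dimension is the 51 sub-domain channels
  img <- RNifti::readNifti(path)
  expect_equal(dim(img)[4], 51L)
  back <- read_pdf4d(path)
  expect_true(grid_equal(back$grid, pdf$grid))
  expect_identical(back$n_foci, pdf$n_foci)
  for (b in c(1L, 14L, 51L)) {
    expect_equal(back$channels[[b]]$idx, pdf$channels[[b]]$idx)
    expect_equal(back$channels[[b]]$val, pdf$channels[[b]]$val,
                 tolerance = 1e-12)
  }
  # without the sidecar the focus totals N_b are lost: hard error
  file.remove(paste0(path, ".json"))
  expect_error(read_pdf4d(path), "sidecar")
})

test_that("in-grid totals agree between 1-mm and 2-mm builds", {
  set.seed(9)
  box <- rbind(c(-20, -20, -20), c(20, 20, 20))
  coords <- matrix(runif(300, -19, 19), ncol = 3)
  tab <- coords_table(coords, subdomain_id = 7L)
  p1 <- assemble_pdf4d(tab, grid_spec(1, box = box))
  p2 <- assemble_pdf4d(tab, grid_spec(2, box = box))
  expect_equal(p1$n_foci[7], 100L)
  expect_equal(p2$n_foci[7], 100L)
  expect_equal(sum(p1$channels[[7]]$val), 1, tolerance = 1e-12)
  expect_equal(sum(p2$channels[[7]]$val), 1, tolerance = 1e-12)
  # the 1-mm build resolves at least as many distinct voxels
  expect_gte(length(p1$channels[[7]]$idx), length(p2$channels[[7]]$idx))
})
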